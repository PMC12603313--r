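# R-side wrappers for the compiled DP kernels (registered in src/init.cpp).

.nussinov_fold <- function(seq, min_loop) {
  .Call(`_miraux_nussinov_fold`, seq, min_loop)
}

.site_align <- function(mirna, window) {
  .Call(`_miraux_site_align`, mirna, window)
}

.site_scan <- function(mirna, transcript, max_bulge, max_penalty) {
  .Call(`_miraux_site_scan`, mirna, transcript, max_bulge, max_penalty)
}
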