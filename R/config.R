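#' Pipeline configuration defaults
#'
#' Returns the full flat configuration used across the pipeline, with every
#' threshold named. Values passed in `...` override defaults. Thresholds are
#' deliberately exposed because the domain-call criteria (e.g. what counts as
#' a "high-quality" F-box) are conventions, not measurements.
#'
#' @param ... named overrides.
#' @return Named list of class `"miraux_config"`.
#' @details Key defaults:
#' * `min_aa = 50`: minimum ORF length (residues).
#' * `gap_open = 10`, `gap_extend = 1`, `substitution_matrix = "BLOSUM62"`.
#' * `fbox_min_identity = 0.35`, `lrr_min_coverage = 0.80`: TIR1/AFB calls.
#' * `ac_positions`: taken from the packaged reference configuration.
#' * `dbd_max_mismatch = 1`: tolerated literal mismatches in the
#'   `SxxxxHGxxSxxR` motif (detects the ARF17/18-type H->G variant).
#' * `dd_min_identity = 0.35`, `pb1_min_identity = 0.30`.
#' * `md_min_len = 40`, `q_min = 0.10`, `pg_min = 0.15`, `top_k = 4`:
#'   middle-domain activator/repressor rule.
#' * `min_loop = 3`, `max_window = 400`, `flank = 150`,
#'   `min_paired_frac = 0.6`, `max_mismatch = 0`: precursor validation.
#' * `rho_threshold = 0.5` (strict `>`): precursor-miRNA expression filter.
#' * `max_bulge = 2`, `max_penalty = 4.5`, `max_category = 4`: target scan
#'   and degradome confirmation.
#' * `alpha = 0.05`: group-test significance level.
#' @export
miraux_config <- function(...) {
  cfg <- list(
    min_aa = 50,
    substitution_matrix = "BLOSUM62",
    gap_open = 10,
    gap_extend = 1,
    fbox_min_identity = 0.35,
    lrr_min_coverage = 0.80,
    dbd_max_mismatch = 1,
    dd_min_identity = 0.35,
    pb1_min_identity = 0.30,
    md_min_len = 40,
    q_min = 0.10,
    pg_min = 0.15,
    top_k = 4,
    min_loop = 3,
    max_window = 400,
    flank = 150,
    min_paired_frac = 0.6,
    max_mismatch = 0,
    rho_threshold = 0.5,
    max_bulge = 2,
    max_penalty = 4.5,
    max_category = 4,
    alpha = 0.05)
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0 || is.null(names(over)) || any(!nzchar(names(over)))) {
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  structure(cfg, class = "miraux_config")
}

#' Validate a configuration
#'
#' Checks types, ranges and sign constraints before any computation runs.
#'
#' @param cfg configuration list.
#' @return `cfg`, invisibly; errors name the offending key.
#' @export
validate_config <- function(cfg) {
  num_keys <- setdiff(names(cfg), "substitution_matrix")
  for (k in num_keys) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      stop("configuration key ", sQuote(k), " must be a single number",
           call. = FALSE)
    }
  }
  nonneg <- c("gap_open", "gap_extend", "max_mismatch", "max_bulge",
              "max_penalty", "max_category")
  for (k in nonneg) if (cfg[[k]] < 0) {
    stop("configuration key ", sQuote(k), " must be >= 0", call. = FALSE)
  }
  frac <- c("fbox_min_identity", "lrr_min_coverage", "dd_min_identity",
            "pb1_min_identity", "q_min", "pg_min", "min_paired_frac", "alpha")
  for (k in frac) if (cfg[[k]] < 0 || cfg[[k]] > 1) {
    stop("configuration key ", sQuote(k), " must be in [0, 1]", call. = FALSE)
  }
  if (cfg$min_aa < 1) stop("configuration key 'min_aa' must be >= 1",
                           call. = FALSE)
  if (cfg$min_loop < 3) stop("configuration key 'min_loop' must be >= 3",
                             call. = FALSE)
  if (cfg$rho_threshold < -1 || cfg$rho_threshold > 1) {
    stop("configuration key 'rho_threshold' must be in [-1, 1]", call. = FALSE)
  }
  invisible(cfg)
}
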