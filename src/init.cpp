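// Symbol registration for the compiled DP kernels.

#include <Rcpp.h>
using namespace Rcpp;

List nussinov_fold(std::string seq, int min_loop);
RcppExport SEXP _miraux_nussinov_fold(SEXP seqSEXP, SEXP min_loopSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< std::string >::type seq(seqSEXP);
    Rcpp::traits::input_parameter< int >::type min_loop(min_loopSEXP);
    rcpp_result_gen = Rcpp::wrap(nussinov_fold(seq, min_loop));
    return rcpp_result_gen;
END_RCPP
}

List site_align(std::string mirna, std::string window);
RcppExport SEXP _miraux_site_align(SEXP mirnaSEXP, SEXP windowSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< std::string >::type mirna(mirnaSEXP);
    Rcpp::traits::input_parameter< std::string >::type window(windowSEXP);
    rcpp_result_gen = Rcpp::wrap(site_align(mirna, window));
    return rcpp_result_gen;
END_RCPP
}

DataFrame site_scan(std::string mirna, std::string transcript,
                    int max_bulge, double max_penalty);
RcppExport SEXP _miraux_site_scan(SEXP mirnaSEXP, SEXP transcriptSEXP,
                                  SEXP max_bulgeSEXP, SEXP max_penaltySEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< std::string >::type mirna(mirnaSEXP);
    Rcpp::traits::input_parameter< std::string >::type transcript(transcriptSEXP);
    Rcpp::traits::input_parameter< int >::type max_bulge(max_bulgeSEXP);
    Rcpp::traits::input_parameter< double >::type max_penalty(max_penaltySEXP);
    rcpp_result_gen = Rcpp::wrap(site_scan(mirna, transcript, max_bulge, max_penalty));
    return rcpp_result_gen;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
    {"_miraux_nussinov_fold", (DL_FUNC) &_miraux_nussinov_fold, 2},
    {"_miraux_site_align", (DL_FUNC) &_miraux_site_align, 2},
    {"_miraux_site_scan", (DL_FUNC) &_miraux_site_scan, 4},
    {NULL, NULL, 0}
};

RcppExport void R_init_miraux(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
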