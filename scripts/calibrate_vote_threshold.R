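#!/usr/bin/env Rscript
# Calibration of the verifast vote threshold: sweep the threshold on the
# default synthetic benchmark and report the false-positive rate (reported
# hits absent from the full-DP TRUE set). The shipped constant
# (VERIFAST_VOTE_THRESHOLD) is the smallest threshold whose rate falls in
# the low single percents.

suppressPackageStartupMessages(library(sansearch))

bm <- make_benchmark(benchmark_spec())
idx <- sans_index(bm$db)
truth <- build_true_set(bm$queries, idx$db)

cat("threshold\tfp_rate\thits\n")
for (th in 1:5) {
  hits <- sans_search_set(bm$queries, idx,
                          search_params(mode = "verifast", vote_threshold = th))
  cat(sprintf("%d\t%.4f\t%d\n", th, false_positive_rate(hits, truth),
              sum(vapply(hits, nrow, 1L))))
}
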