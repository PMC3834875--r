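# shared fixtures: hand-built prediction sets and brute-force oracles

make_preds <- function(prob, label, model = "toy") {
  structure(data.frame(id = sprintf("P%03d", seq_along(prob)),
                       prob = prob, label = label,
                       fold = NA_integer_, model = model,
                       stringsAsFactors = FALSE),
            class = c("prediction_set", "data.frame"))
}

# exhaustive pairwise Mann-Whitney AUC: independent of the package path
auc_pairwise_oracle <- function(prob, label) {
  pos <- prob[label == 1]; neg <- prob[label == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small cohort with a strong planted PSA effect on NOC status
planted_cohort <- function(n = 400, seed = 11) {
  p <- default_params(n = n, seed = seed)
  co <- sample_cohort(p)
  # replace the outcome with one strongly driven by PSA
  set.seed(seed + 1)
  pr <- stats::plogis(-3 + 0.4 * co$psa)
  noc <- stats::runif(n) < pr
  co$path_stage <- factor(ifelse(noc, "ECE", "OC"), PATH_STAGE_LEVELS)
  co$noc <- noc
  co
}
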