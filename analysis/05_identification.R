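#!/usr/bin/env Rscript
# Privacy flip side: identify the user (rather than the PIN) from the
# real-PIN epochs of a seven-user cohort, with the same density and PI
# machinery (U in place of P), and compare against the PIN-recovery PI.

suppressPackageStartupMessages(library(erpleak))
dir.create("results", showWarnings = FALSE)

seed <- 20260101
cohort <- simulate_cohort(7, seed = seed)
obs <- vector("list", 7)
pin_pi <- numeric(7)
for (u in 1:7) {
  obs[[u]] <- select_concat(reject_artifacts(bandpass(cohort[[u]]$session))$epochs)
  cohort[[u]]$session <- NULL
  pin_pi[u] <- estimate_pi(NULL, as.integer(obs[[u]]$tags == 1L),
                           seed = derive_seed(seed, 400L + u),
                           obs = obs[[u]],
                           basis_spec = list(variant = "average",
                                             n_d = 5))$pi
}

id <- identify_user(obs, k = 10, seed = derive_seed(seed, 500L))
tab <- data.frame(user = 1:7, partial_pi = unname(id$partial),
                  pin_pi = pin_pi)
write.csv(tab, "results/identification_pi.csv", row.names = FALSE)

cat("Partial identification PI per user (H[U] = log2(7) = 2.807 bits)\n")
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nOverall PI(U;O) = %.3f bits, 90%% CI [%.3f, %.3f]\n",
            id$overall$pi, id$overall$ci_low, id$overall$ci_high))
cat(sprintf("Mean PIN-recovery PI(P;O) = %.3f bits\n", mean(pin_pi)))
if (id$overall$pi > mean(pin_pi)) {
  cat("The EEG is more informative about who is watching than about\n")
  cat("which code is theirs for this cohort.\n")
} else {
  cat("For this cohort draw, identity information is comparable to (not\n")
  cat("above) the PIN information; identification grows with larger\n")
  cat("inter-user variability or lower noise (see the 4-user low-noise\n")
  cat("comparison in the test suite, where PI(U;O) clearly dominates).\n")
}
cat("\nConfusion (true x decoded):\n")
print(id$confusion)
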