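# Shared fixtures: the two reference parameterizations used throughout the
# suite (feedback model with the single-cell mean pinned at 100; partitioning
# model with mean 20 and gamma = ln 2).

fb_params <- function(k = 0.01, target = 100, beta = 10, gamma = 1) {
  burst_params(burst_frequency_for_mean(target, k, beta, gamma),
               beta, gamma, k = k)
}

pt_params <- function(beta = 10, target = 20, gamma = log(2)) {
  burst_params(gamma * target / beta, beta, gamma, k = 0)
}

# standard error of a difference of two independent estimates
se_diff <- function(se1, se2) sqrt(se1^2 + se2^2)
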