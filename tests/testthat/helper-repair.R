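# shared fixtures, all built in code
ref_rates <- function() rate_constants(k_s = 0.21, k_d = 0.74)
ref_init <- function() compartment_state(S = 0, L = 0.05, LSSB = 0.95, CSSB = 0)

noiseless_data <- function(n_replicates = 1) {
  generate_dataset(reference_config(noise_sd = 0,
                                    n_replicates = n_replicates))
}

# tiny hand-rolled measurement table
toy_table <- function(values, observable = "supercoiled", time_h = 2,
                      condition = "control") {
  data.frame(condition = condition, time_h = time_h,
             replicate = seq_along(values), observable = observable,
             value = values)
}

# draw a random valid model setup (rates, init) under the current RNG
random_setup <- function(rate_range = c(0.05, 2)) {
  k <- stats::runif(4, rate_range[1], rate_range[2])
  w <- stats::rexp(4)
  init <- do.call(compartment_state,
                  as.list(stats::setNames(w / sum(w),
                                          c("S", "L", "LSSB", "CSSB"))))
  list(rates = rate_constants(k_s = k[1], k_sd = k[2], k_d = k[3],
                              k_ds = k[4], tied = FALSE),
       init = init)
}
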