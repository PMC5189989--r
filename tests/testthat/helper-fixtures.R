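# Shared fixtures: the four reference parameter sets and small helpers.

s_male <- function() pk_params(V = 55.3, CL = 253, Ka = 0.241, Tlag = 0.67)
s_female <- function() pk_params(V = 34.9, CL = 101, Ka = 0.161, Tlag = 0.38)

single_100 <- function() dosing_regimen(100, 0)
q12h_x9 <- function() dosing_regimen(100, seq(0, 96, by = 12))

# random but physiologically plausible parameter sets for property tests
random_params <- function(n) {
  lapply(seq_len(n), function(i) {
    pk_params(V = exp(runif(1, log(10), log(200))),
              CL = exp(runif(1, log(20), log(500))),
              Ka = exp(runif(1, log(0.05), log(5))),
              Tlag = runif(1, 0, 1.5))
  })
}
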