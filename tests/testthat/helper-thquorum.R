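## shared fixtures: everything is generated in code, nothing is stored

par_default <- model_parameters()
par_quiet <- model_parameters(n_TF1 = 0, n_TF2 = 0, n_CY1 = 0, n_CY2 = 0)

## a deliberately asymmetric but valid parameter set
par_asym <- model_parameters(p1 = 11, p2 = 9, s1 = 6.5, s2 = 7.5,
                             X1 = 55, X2 = 65)

random_states <- function(n, seed = 1) {
  set.seed(seed)
  matrix(stats::rexp(4 * n, rate = 1 / 30), ncol = 4)
}

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

## swap of the Th1 and Th2 axes, for index-symmetry properties
swap_state <- function(x) unname(x)[c(2, 1, 4, 3)]
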