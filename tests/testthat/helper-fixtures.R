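# shared fixtures built in code

unconstrained_bounds <- function(q, eps = 0) {
  component_bounds(paste0("x", seq_len(q)),
                   lower = rep(eps, q), upper = rep(1, q))
}

# random feasible design by uniform simplex draws (unconstrained region)
random_simplex_design <- function(n, q, seed) {
  set.seed(seed)
  e <- matrix(rexp(n * q), ncol = q)
  mixture_design(e / rowSums(e))
}

paper_bounds <- lnp_bounds
paper_design <- builtin_design
paper_models <- builtin_models

# modeling rows only, as a plain proportion matrix
training_rows <- function(design = builtin_design()) {
  design$x[!design$is_validation, , drop = FALSE]
}

# noiseless response tables from the built-in ground truth
noiseless_responses <- function(design = builtin_design()) {
  simulate_responses(design, seed = 1,
                     sigma = c(encapsulation_pct = 0, diameter_nm = 0,
                               nmfi = 0))
}

all_pair_terms <- function(q) utils::combn(q, 2, simplify = FALSE)
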