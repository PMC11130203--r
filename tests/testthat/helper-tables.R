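# small reaction tables built in code for unit tests

toy_roles <- function(p_nuc = 2, p_imi = 1, p_solv = 0, p_cat = 0) {
  nm <- c(if (p_solv) paste0("s", seq_len(p_solv)),
          if (p_cat) paste0("cat", seq_len(p_cat)),
          if (p_nuc) paste0("nuc", seq_len(p_nuc)),
          if (p_imi) paste0("imi", seq_len(p_imi)))
  stats::setNames(rep(c("solvent", "catalyst", "nucleophile", "imine"),
                      c(p_solv, p_cat, p_nuc, p_imi)), nm)
}

toy_table <- function(n = 12, seed = 1, target = NULL, p_nuc = 2, p_imi = 1,
                      p_solv = 0, p_cat = 0) {
  set.seed(seed)
  roles <- toy_roles(p_nuc, p_imi, p_solv, p_cat)
  x <- matrix(rnorm(n * length(roles)), n,
              dimnames = list(NULL, names(roles)))
  if (is.null(target)) target <- rnorm(n)
  reaction_table(x, roles, target = target)
}

# linear table: y = x %*% beta (+ noise), p features all nucleophile/imine
linear_table <- function(n, beta, noise = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  roles <- toy_roles(p_nuc = ceiling(p / 2), p_imi = floor(p / 2))
  x <- matrix(rnorm(n * p), n, dimnames = list(NULL, names(roles)))
  y <- as.numeric(x %*% beta) + rnorm(n, 0, noise)
  reaction_table(x, roles, target = y)
}
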