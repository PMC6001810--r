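# Small hand-built fixtures shared across test files.

# a well-formed two-person, three-visit panel
toy_panel <- function() {
  as_panel(data.frame(
    id = rep(1:2, each = 3),
    visit = rep(0:2, 2),
    x = c(0, 1, 1, 0, 0, 1),
    y_cont = c(80, 82, 85, 90, 88, 87),
    y_count = c(4, 0, 2, 0, 1, 0),
    age = rep(c(12, 30), each = 3),
    observed = 1L))
}

# single-visit point-treatment panel with one binary confounder (coded into
# the age column) and treatment probability depending on it
point_panel <- function(n = 4000, seed = 7, tau = 3) {
  set.seed(seed)
  z <- rbinom(n, 1, 0.4)
  x1 <- rbinom(n, 1, ifelse(z == 1, 0.7, 0.3))
  y0 <- rnorm(n, 70, 5) + 8 * z
  y1 <- y0 + rnorm(n, 0, 4) + tau * x1 + 2 * z
  as_panel(data.frame(
    id = rep(seq_len(n), each = 2),
    visit = rep(0:1, n),
    x = as.vector(rbind(0L, x1)),
    y_cont = as.vector(rbind(y0, y1)),
    y_count = 0L,
    age = rep(z, each = 2),
    observed = 1L))
}

# nonparametric standardization over the binary confounder
standardized_diff <- function(panel) {
  d <- panel[panel$visit == 1, ]
  pz <- tapply(rep(1, nrow(d)), d$age, sum) / nrow(d)
  cells <- tapply(d$y_cont, list(d$x, d$age), mean)
  sum((cells["1", ] - cells["0", ]) * pz[colnames(cells)])
}

# a hand-specified zinb fitted_model (predict/sample need only terms,
# coefficients and theta)
hand_zinb <- function(zero_coef, count_coef, theta, formula_rhs) {
  tpl <- stats::terms(stats::as.formula(paste("~", formula_rhs)))
  m <- tdcausal:::new_fitted_model(
    "zinb",
    coefficients = count_coef,
    converged = TRUE,
    terms = tpl,
    zero = list(coefficients = zero_coef, terms = tpl),
    theta = theta)
  m
}
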