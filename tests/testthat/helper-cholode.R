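# Shared fixtures, memoized so expensive objects are built once per run.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

toy_net <- function() memo("toy_net", toy_pkn())
toy_tab <- function() memo("toy_tab", default_parameters(toy_net(), fix_tau = TRUE))
toy_truth <- function() memo("toy_truth", generate_ground_truth(
  toy_net(), seed = 42, conditions = toy_conditions(), par_table = toy_tab()))
toy_data_clean <- function() memo("toy_data_clean", simulate_dataset(
  toy_net(), toy_truth(), cv = 0, bio_replicates = 1, seed = 7))
chol_net <- function() memo("chol_net", cholesterol_pkn())

# Normalized Hill transfer written out independently of the package.
hill_oracle <- function(x, k, n) {
  ifelse(x == 0, 0, x^n * (1 + k^n) / (x^n + k^n))
}

# Hand-coded toy-network right-hand side, written directly from the model
# equations (independent of the package's compiled RHS). State order:
# TF, P1, P2, M1, M2, M3; inputs S and D; tau = 1 throughout.
toy_rhs_oracle <- function(x, S, D, p) {
  f <- function(v, src, tgt) hill_oracle(
    min(max(v, 0), 1),
    p[[sprintf("k_%s_%s", src, tgt)]], p[[sprintf("n_%s_%s", src, tgt)]])
  mm <- p[["k4"]] * min(max(x[["P2"]], 0), 1) * x[["M2"]] /
    (p[["kM4"]] * (1 + D / p[["kI"]]) + x[["M2"]])
  c(TF = f(S, "S", "TF") - x[["TF"]],
    P1 = f(x[["TF"]], "TF", "P1") - x[["P1"]],
    P2 = f(x[["TF"]], "TF", "P2") - x[["P2"]],
    M1 = p[["k1"]] - p[["k2"]] * x[["P1"]] * x[["M1"]] -
      p[["k3"]] * x[["M1"]],
    M2 = p[["k2"]] * x[["P1"]] * x[["M1"]] - mm,
    M3 = mm - p[["k5"]] * x[["M3"]])
}

# Fixed-step Euler integration of an arbitrary derivative function.
euler_integrate <- function(rhs, x0, t_end, dt) {
  x <- x0
  n <- ceiling(t_end / dt)
  for (i in seq_len(n)) {
    x <- x + dt * rhs(x)
    x <- pmax(x, 0)
  }
  x
}

named_params <- function(tab) stats::setNames(tab$value, tab$name)
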