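# Independent oracles: build the circuit impedance from naive complex
# series/parallel component combination, never from the closed forms under
# test.

parallel_z <- function(z1, z2) z1 * z2 / (z1 + z2)

naive_eric_z <- function(p, f) {
  w <- 2 * pi * f
  zc <- 1 / (1i * w * p[["Cp"]])          # peripheral compliance
  p[["Rc"]] + 1i * w * p[["I"]] + parallel_z(p[["Rp"]], zc)
}

naive_aric_z <- function(p, f) {
  w <- 2 * pi * f
  parallel_z(naive_eric_z(p, f), 1 / (1i * w * p[["Ce"]]))
}

# random strictly positive eRIC parameter draws in a physiological box
rand_eric <- function(n, seed = 1) {
  set.seed(seed)
  replicate(n, c(Rc = runif(1, 0.1, 1), I = runif(1, 5e-4, 5e-3),
                 Rp = runif(1, 0.1, 1.5), Cp = runif(1, 0.02, 0.3)),
            simplify = FALSE)
}

# brute-force trapezoid of |X| on a very fine linear grid, for AX checks
brute_ax <- function(spectrum, upper) {
  f <- seq(5, upper, length.out = 20001)
  x <- abs(vapply(f, function(fi) value_at(spectrum, fi, "reactance"),
                  numeric(1)))
  sum(diff(f) * (head(x, -1) + x[-1]) / 2)
}
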