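# Small fixture schemes built in code.

# one b0 + three orthogonal directions at a single shell
tiny_scheme <- function(b = 3000, delta = 19, Delta = 36) {
  acquisition_scheme(b = c(0, b, b, b),
                     directions = rbind(c(0, 0, 0), diag(3)),
                     delta = delta, Delta = Delta)
}

# two-shell scheme with a handful of directions per shell
small_multishell <- function(delta = 10, Delta = 25) {
  dirs6 <- repulsion_directions(6, seed = 3)
  acquisition_scheme(b = c(0, 0, rep(1000, 6), rep(3000, 6)),
                     directions = rbind(matrix(0, 2, 3), dirs6, dirs6),
                     delta = delta, Delta = Delta)
}

expect_fractions_sum_to_one <- function(fit) {
  expect_equal(fit$f_soma + fit$f_neurite + fit$f_extra, 1,
               tolerance = 1e-9)
}
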