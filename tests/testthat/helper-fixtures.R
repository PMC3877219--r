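# Shared helpers: cached parameter set, rigid-body motions, a hand-rolled
# Pearson correlation used as an independent oracle.

test_params <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- shift_params()
    p
  }
})

# rigid rotation + translation of a whole structure
rigid_move <- function(s, axis = c(1, 2, 3), angle = 25, shift = c(3, -2, 5)) {
  R <- amideshift:::rotation_about_axis(axis, angle)
  set_coords(s, sweep(coords(s) %*% t(R), 2, shift, "+"))
}

# explicit-sum Pearson correlation (oracle, independent of stats::cor)
pearson_manual <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# synthetic one-ring table for term-level tests
one_ring <- function(center, normal, kind = "PHE6") {
  normal <- normal / sqrt(sum(normal^2))
  tibble::tibble(
    resno = 1L, kind = kind,
    cx = center[1], cy = center[2], cz = center[3],
    nx = normal[1], ny = normal[2], nz = normal[3]
  )
}
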