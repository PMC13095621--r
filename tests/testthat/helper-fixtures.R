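# Shared fixtures, built in code.

# lower semicircle of radius r: exact chord 2r, depth r, margin-to-apex
# lengths r*sqrt(2)
semicircle_profile <- function(r = 5, n = 201, plane = "sagittal") {
  th <- seq(pi, 2 * pi, length.out = n)
  as_profile(data.frame(s = r * cos(th), h = r * sin(th)), plane)
}

parabola_profile <- function(depth = 2, half = 10, n = 201, plane = "sagittal") {
  s <- seq(-half, half, length.out = n)
  as_profile(data.frame(s = s, h = -depth * (1 - (s / half)^2)), plane)
}

single_facet_ascii <- function(path) {
  writeLines(c(
    "solid minimal",
    "  facet normal 0 0 1",
    "    outer loop",
    "      vertex 0 0 0",
    "      vertex 1 0 0",
    "      vertex 0 1 0",
    "    endloop",
    "  endfacet",
    "endsolid minimal"), path)
  path
}

# independent Freeman-Halton oracle for 2xC tables: enumerate the first row
# cell-by-cell, probability from products of binomial coefficients
fh_oracle_2xc <- function(m) {
  stopifnot(nrow(m) == 2)
  ct <- colSums(m); r1 <- sum(m[1, ]); n <- sum(m)
  logp <- function(a) sum(lchoose(ct, a)) - lchoose(n, r1)
  cells <- expand.grid(lapply(ct, function(x) 0:x))
  cells <- cells[rowSums(cells) == r1, , drop = FALSE]
  lps <- apply(cells, 1, logp)
  lobs <- logp(m[1, ])
  sum(exp(lps[lps <= lobs + 1e-12 * abs(lobs)]))
}
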