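# Shared fixtures: the population-average HeLa cell of the readout-curve
# fit and a few reference cantilevers. Built in code, never stored.

hela_cell <- function(mass = 3.14e-12, f = 14.4e3, q = 0.3) {
  CellMechanicalModel(mass, eigenfrequency = f, qualityFactor = q)
}

# high-Q lever for oracle-equivalence checks (mass loading resolvable)
cant_75k <- function(k = 8, q = 100) CantileverModel(k, 75e3, q)

# coarser grids keep the virtual sweep experiments fast in tests without
# losing the accuracy the assertions need
fast_grid <- list(n = 501L, refineN = 401L)

# independent hand evaluation of the readout-accuracy law, written as the
# plain arithmetic of the formula (kHz^4 units like the derivation notes)
readout_by_hand <- function(f_cant_khz, f_cell_khz, q) {
  x <- f_cell_khz^2
  f2 <- f_cant_khz^2
  1 + f2 * (x - f2) / ((x - f2)^2 + f2 * x / q^2)
}
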