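# shared fixtures built in code

# 2x2 landscape: one of each roost/scaring/accommodation/nature
tiny_land <- function(initial_height = 0.094)
  new_landscape(matrix(c(-1L, 2L, 1L, 3L), 2, 2),
                initial_height = initial_height)

# uniform grassland square with a single roost corner, for behaviour tests
grass_land <- function(n = 21L, type = 1L, initial_height = 0.094) {
  g <- matrix(type, n, n)
  g[1L, 1L] <- -1L
  new_landscape(g, initial_height = initial_height)
}

default_sp <- default_species()

# brute-force OLS oracle via the normal equations
ols_oracle <- function(X, y) solve(crossprod(X), crossprod(X, y))
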