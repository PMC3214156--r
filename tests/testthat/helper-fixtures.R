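# Shared fixtures: the standard NA = 0.22 fiber in air at several core sizes,
# and the default multi-fiber arrangement (10 um spacing).

std_fiber <- function(core_size) fiber_spec(core_size, 0.22, 1.0)

single_probe <- function(distance = 0, tilt = 0, dialect = "as_printed") {
  probe_config("single", distance = distance, tilt = tilt, dialect = dialect)
}

multi_probe <- function(distance = 0, tilt = 0, spacing = 10,
                        dialect = "as_printed") {
  probe_config("multi", distance = distance, tilt = tilt,
               fiber_spacing = spacing, dialect = dialect)
}

# Reference value of tan(theta) for NA = 0.22 in air, computed from the
# definition (independent of package internals).
TAN_THETA_022 <- 0.22 / sqrt(1 - 0.22^2)

# Independent brute-force evaluation of the multi-fiber efficiency at normal
# incidence, written directly from the formulas (vectorized over d).  Used
# as the oracle for the optimizer tests.
brute_multi_efficiency <- function(d, size, spacing, dialect = "as_printed") {
  t <- TAN_THETA_022
  spot <- size + d * t
  omega <- 1 - d / sqrt(d^2 + size^2)
  cc <- size + spacing
  ov <- numeric(length(d))
  open <- spot > cc
  u <- cc / spot[open]
  lead <- if (dialect == "as_printed") 4 else 2
  ov[open] <- lead * acos(u) / pi -
    2 * cc * sqrt(spot[open]^2 - cc^2) / (pi * spot[open]^2)
  if (dialect == "as_printed") ov <- pmin(pmax(ov, 0), 1)
  kernel <- if (dialect == "as_printed") (spot / size)^2 * omega else omega
  kernel * ov
}
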