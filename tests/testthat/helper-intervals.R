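# The published summary tables print mean squares rounded to (at most) 3
# decimals. For golden tests, a derived statistic can only be reproduced to
# the precision those inputs carry, so each check combines a strict
# 3-decimal comparison (where the rounded inputs support it) with interval
# containment: the printed value must lie inside the statistic's range over
# mean squares within +/- half an ulp of the printed values.

h2_interval <- function(msf, mse, half = 5e-4) {
  c(lo = 1 - (mse + half) / (msf - half),
    hi = 1 - (mse - half) / (msf + half))
}

# range of |h2_s / h2_n| over the two input intervals (evaluated at the
# corners; the ratio is monotone in each argument while the denominator
# interval keeps one sign, which holds for every table row)
sibh_interval <- function(int_n, int_s) {
  stopifnot(prod(sign(int_n)) > 0)
  corners <- abs(outer(int_s, 1 / int_n))
  c(lo = min(corners), hi = max(corners))
}
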