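# Shared internals.

# coefficient covariance of a linear fit; exact (zero-residual) oracle data
# triggers summary.lm's "essentially perfect fit" warning, which carries no
# information here
.lm_vcov <- function(fit) suppressWarnings(stats::vcov(fit))
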