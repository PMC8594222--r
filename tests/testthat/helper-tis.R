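# Shared fixtures: the calibrated experimental arms.

sched_control <- function() tis_schedule()
sched_5fu <- function() tis_schedule(fivefu_days = 1:4)
sched_cd25 <- function() tis_schedule(anticd25_days = c(3, 6, 10, 13, 17, 20))
sched_comb <- function() tis_schedule(fivefu_days = 1:4,
                                      anticd25_days = c(3, 6, 10, 13, 17, 20))

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)
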