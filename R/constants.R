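# Fixed vocabularies shared across modules (loaded before the files that
# use them at top level).

COMPONENTS <- c("C", "F", "LRNC")

MR_CHANNELS <- c("t1w2d", "pdw", "tof", "t1w3d_pre", "t1w3d_post")
ALL_CHANNELS <- c(MR_CHANNELS, "cta")

FEATURE_SUBSETS <- c("all", "mri", "cta", "distances",
                     "mri+distances", "cta+distances")
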