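# Shared vocabularies for the model's state space and parameter tables.

AGE_GROUP_LABELS <- c("45-49", "50-54", "55-59", "60-64",
                      "65-69", "70-74", "75-79", "80+")
AGE_GROUP_LOWER <- c(45L, 50L, 55L, 60L, 65L, 70L, 75L, 80L)

TRANSITION_NAMES <- c("r_none_to_na", "r_na_to_adv",
                      "r_adv_to_pre", "r_pre_to_clin")

UNDIAG_STATES <- c("no_lesion", "nonadv_adenoma",
                   "adv_adenoma", "preclinical_crc")
SURV_STRATA <- c("routine", "post_polypectomy_na", "post_polypectomy_adv")
SCREEN_STRATA <- c("screen0", "screen1_negative", "screen2", "off_track")
DETECTION_MODES <- c("screen_detected", "clinically_detected")
CRC_PHASES <- c("diagnosis_treatment", "remission", "metastatic_terminal")

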