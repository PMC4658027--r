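# Named constants shared across the package. Every coefficient is stored once,
# to full printed precision, and referenced from here.

# Conversion between empty body weight and shrunk body weight: EBW = 0.891 * SBW.
EBW_PER_SBW <- 0.891

# Shrunk-weight gain to empty-body gain: EBG = 0.956 * SWG.
EBG_PER_SWG <- 0.956

# Standard reference weight (kg shrunk BW) of a steer at 28 % empty body fat,
# used to size-scale retained-energy requirements.
SRW_DEFAULT <- 478

# kg of AFSBW per percentage point of empty body fat away from the target.
KG_PER_PCT_EBF <- 14.26

# Default empty-body-fat endpoint (%, USDA low Choice).
TARGET_EBF_DEFAULT <- 28

# BIF frame-score polynomials (hip height in cm, age in days), valid 5-21 mo.
FS_BULL <- c(intercept = -11.548, hh = 0.1920, age = -0.0289,
             age2 = 0.00001947, hh_age = 0.00001315)
FS_FEMALE <- c(intercept = -11.7086, hh = 0.1859, age = -0.0239,
               age2 = 0.0000146, hh_age = 0.00002988)
FS_AGE_RANGE <- c(150, 640)

# AFSBW (kg at 28 % EBF) as a linear function of frame score, by sex class.
AFSBW_LINES <- list(
  bull   = c(slope = 40.0, intercept = 440.0),
  steer  = c(slope = 33.4, intercept = 366.6),
  heifer = c(slope = 26.7, intercept = 293.2)
)

# Empty body fat (%) from carcass traits; the first form needs ribeye area.
EBF_WITH_REA <- c(intercept = 17.76207, ft = 4.68142, hcw = 0.01945,
                  ms = 0.81855, rea = -0.06754)
EBF_NO_REA <- c(intercept = 14.08796, ft = 4.7135, hcw = 0.01316, ms = 0.90855)

# Empty body weight (kg) from hot carcass weight.
EBW_FROM_HCW <- c(intercept = 32.39, hcw = 1.316)

# ME (Mcal/kg) -> net energy for maintenance / gain (Mcal/kg), cubic forms.
NEM_FROM_ME <- c(me = 1.37, me2 = -0.138, me3 = 0.0105, intercept = -1.12)
NEG_FROM_ME <- c(me = 1.42, me2 = -0.174, me3 = 0.0122, intercept = -1.65)

# Maintenance requirement: NEm_req (Mcal/d) = 0.077 * SBW^0.75.
MAINT_COEF <- 0.077

# Retained energy: RE = 0.0635 * (0.891*EQSBW)^0.75 * (0.956*ADG)^1.097.
RE_COEF <- 0.0635
RE_W_EXP <- 0.75
RE_G_EXP <- 1.097

# Empirical dry matter intake for growing cattle:
# DMI = SBW^0.75 * (0.2435*NEm - 0.0466*NEm^2 - 0.0869) / NEm.
DMI_EMP <- c(nem = 0.2435, nem2 = -0.0466, intercept = -0.0869)

# NEm (Mcal/kg) assumed by the end-BW intake stub.
DMI_ENDBW_NEM <- 2.2

# Names of the 11 molecular breeding value score columns.
MBV_COLUMNS <- c("mbv_cab_mrb", "mbv_adg", "mbv_hcw", "mbv_rea",
                 "mbv_snp50_mrb", "mbv_snp50_rea", "mbv_all_mrb",
                 "mbv_all_rea", "mbv_all_adg", "mbv_all_rfi", "mbv_bt_rfi")

LEPTIN_GENOTYPES <- c("CC", "CT", "TT")

# Continuous traits the cohort generator draws, in copula column order.
COHORT_VARS <- c("isbw_kg", "hip_height_cm", "final_bw_kg", "dof_d",
                 "adg_kg_d", "hcw_kg", "ft_cm", "rea_cm2", "marbling",
                 MBV_COLUMNS)

# sex indicator used throughout the adjustment equations: 0 = steer, 1 = heifer
sex_indicator <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !sex %in% c("steer", "heifer")
  if (any(bad)) {
    abort(paste0("unknown sex value(s): ",
                 paste(unique(sex[bad]), collapse = ", ")))
  }
  as.numeric(sex == "heifer")
}
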