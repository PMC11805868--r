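#' @keywords internal
"_PACKAGE"

# Canonical ordering of the state vector y = [LC, NE_mPFC, mPFC, NTS, NE_NAcc, NAcc].
STATE_NAMES <- c("LC", "NE_mPFC", "mPFC", "NTS", "NE_NAcc", "NAcc")

# The 17 circuit coefficients, in the order they are serialized.
PARAM_NAMES <- c(
  "tau_LC", "alpha_LC_mPFC", "alpha_LC_ext",
  "tau_NE_mPFC", "alpha_mPFC_LC",
  "tau_mPFC", "alpha_mPFC_NE", "alpha_mPFC_ext",
  "tau_NTS", "alpha_NTS_mPFC", "alpha_NTS_ext",
  "tau_NE_NAcc", "alpha_NAcc_LC", "alpha_NAcc_NTS",
  "tau_NAcc", "alpha_NAcc_NE", "alpha_NAcc_ext"
)
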