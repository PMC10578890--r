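#' State alphabets for the categorical pupillary exam
#'
#' The bedside exam records two categorical readings every two hours: pupil
#' size and pupillary light reflex (photo-reactivity). Pupil size takes one
#' of five states -- the normal state (isochoric: equal, normally sized
#' pupils) and four abnormalities (left/right anisochoria, i.e. > 0.5 mm
#' inter-pupil difference; bilateral miosis < 2 mm; bilateral mydriasis
#' > 5 mm). Photo-reactivity takes one of four states -- bilaterally present
#' (normal) and three abnormality levels (bilaterally absent, unilaterally
#' present right or left only).
#'
#' @return `ps_states()` / `pr_states()` return the character vectors of
#'   valid state tokens, normal state first. `ps_normal_state()` /
#'   `pr_normal_state()` return the single normal token.
#' @examples
#' ps_states()
#' pr_normal_state()
#' @export
ps_states <- function() {
  c("ISOCHORIC", "ANISO_LEFT", "ANISO_RIGHT",
    "MIOSIS_BILATERAL", "MYDRIASIS_BILATERAL")
}

#' @rdname ps_states
#' @export
pr_states <- function() {
  c("BILATERAL_PRESENT", "BILATERAL_ABSENT",
    "UNILATERAL_RIGHT", "UNILATERAL_LEFT")
}

#' @rdname ps_states
#' @export
ps_normal_state <- function() "ISOCHORIC"

#' @rdname ps_states
#' @export
pr_normal_state <- function() "BILATERAL_PRESENT"

#' Names of the four dynamical pupillary indices
#'
#' Fixed order used for predictor subsets and output tables: pupil-size
#' jump rate, pupil-size isochoria percentage, photo-reactivity jump rate,
#' photo-reactivity presence percentage. All four live in \[0, 1\].
#'
#' @return Character vector of length 4.
#' @export
index_names <- function() {
  c("ps_jump_rate", "ps_isochoria_pct", "pr_jump_rate", "pr_presence_pct")
}
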