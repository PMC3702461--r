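#' Default tissue parameter table
#'
#' Relaxation times, relative proton density, relative electron density and
#' nominal CT number for the tissues used by the digital phantom.  T1/T2 (T2*
#' for ultrashort-echo rendering of cortical bone) come from the standard
#' literature values for 3 T; relative electron densities are the usual ICRU
#' soft-tissue/bone values.  Nominal HU are bulk assignments consistent with
#' a 140 kVp scale: air -1000, fat -100, yellow marrow -80, muscle +40,
#' cartilage +120, cortical bone +1200; all configurable by editing the
#' returned data frame.
#'
#' \code{fat_like} marks tissues whose signal is nulled by fat saturation.
#'
#' @return A data frame with one row per tissue: \code{name}, \code{t1} (ms),
#'   \code{t2} (ms), \code{proton_density} (relative), \code{electron_density}
#'   (relative), \code{nominal_hu} (HU), \code{fat_like} (logical).
#' @export
tissue_table <- function() {
  tt <- data.frame(
    name             = c("air", "fat", "marrow", "muscle", "cartilage", "bone"),
    t1               = c(1000, 371, 365, 1412, 1156, 200),
    t2               = c(1000, 133, 133, 40, 35, 0.45),
    proton_density   = c(0.00, 1.00, 0.95, 0.70, 0.75, 0.15),
    electron_density = c(0.001, 0.951, 0.982, 1.040, 1.083, 1.781),
    nominal_hu       = c(-1000, -100, -80, 40, 120, 1200),
    fat_like         = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  validate_tissues(tt)
  tt
}

validate_tissues <- function(tt) {
  stopifnot(all(tt$t1 > 0), all(tt$t2 > 0))
  if (any(tt$t2 > tt$t1)) stopf("tissue table invalid: t2 > t1 for %s",
                                paste(tt$name[tt$t2 > tt$t1], collapse = ", "))
  if (any(tt$proton_density < 0)) stopf("proton_density must be >= 0")
  if (any(tt$electron_density <= 0)) stopf("electron_density must be > 0")
  invisible(tt)
}

#' MR sequence parameter set
#'
#' @param kind Sequence family: spin echo, inversion-prepared spoiled
#'   gradient echo, or ultrashort-echo-time spoiled gradient echo.
#' @param te Echo time, ms.
#' @param tr Repetition time, ms.
#' @param flip_angle Excitation flip angle, degrees (0, 90].
#' @param ti Inversion time, ms (inversion_recovery_gre only).
#' @param fat_saturation Null the signal of fat-like tissues?
#' @return An object of class \code{"sequence_params"}.
#' @export
sequence_params <- function(kind = c("spin_echo", "inversion_recovery_gre",
                                     "ute_gre"),
                            te, tr, flip_angle = 90, ti = NA_real_,
                            fat_saturation = FALSE) {
  kind <- match.arg(kind)
  if (!(te < tr)) stopf("te must be < tr")
  if (!(flip_angle > 0 && flip_angle <= 90))
    stopf("flip_angle must be in (0, 90]")
  if (kind == "inversion_recovery_gre" && !is.finite(ti))
    stopf("inversion_recovery_gre requires ti")
  structure(list(kind = kind, te = te, tr = tr, flip_angle = flip_angle,
                 ti = ti, fat_saturation = fat_saturation),
            class = "sequence_params")
}

#' Default eight-contrast acquisition protocol
#'
#' The protocol the phantom generator emulates: three turbo-spin-echo
#' contrasts (proton-density weighted, the same with fat saturation, and
#' T2 weighted), one inversion-prepared T1-weighted gradient echo, and two
#' dual-echo ultrashort-echo-time acquisitions (flip angles 12 and 60
#' degrees) whose first echo at 0.05 ms retains signal from sub-millisecond
#' T2* cortical bone.  Each UTE acquisition contributes two echo images, so
#' the protocol yields eight contrast images.
#'
#' @return Named list of \code{\link{sequence_params}}, one per contrast
#'   image: TSE1, TSE2, TSE3, MPRAGE, UTE1e1, UTE1e2, UTE2e1, UTE2e2.
#' @export
default_protocol <- function() {
  list(
    TSE1   = sequence_params("spin_echo", te = 8.3,  tr = 7500, flip_angle = 90),
    TSE2   = sequence_params("spin_echo", te = 8.3,  tr = 7500, flip_angle = 90,
                             fat_saturation = TRUE),
    TSE3   = sequence_params("spin_echo", te = 75.0, tr = 7500, flip_angle = 90),
    MPRAGE = sequence_params("inversion_recovery_gre", te = 2.38, tr = 2000,
                             flip_angle = 12, ti = 700),
    UTE1e1 = sequence_params("ute_gre", te = 0.05, tr = 7.25, flip_angle = 12),
    UTE1e2 = sequence_params("ute_gre", te = 4.91, tr = 7.25, flip_angle = 12),
    UTE2e1 = sequence_params("ute_gre", te = 0.05, tr = 7.25, flip_angle = 60),
    UTE2e2 = sequence_params("ute_gre", te = 4.91, tr = 7.25, flip_angle = 60)
  )
}

#' Noiseless steady-state MR signal for a tissue under a sequence
#'
#' Standard closed-form steady-state signal equations (no Bloch simulation):
#' \describe{
#'   \item{spin echo}{\eqn{S = PD (1 - e^{-TR/T1}) e^{-TE/T2}}}
#'   \item{spoiled gradient echo (UTE)}{\eqn{S = PD \sin\alpha
#'     \frac{1-E_1}{1-\cos\alpha\, E_1} e^{-TE/T2^*}} with
#'     \eqn{E_1 = e^{-TR/T1}}; the tissue's \code{t2} field is read as T2*}
#'   \item{inversion-prepared gradient echo}{\eqn{S = PD |1 - 2e^{-TI/T1} +
#'     e^{-TR/T1}| e^{-TE/T2}}}
#' }
#' Air (proton density 0) returns 0; fat saturation nulls fat-like tissues.
#'
#' @param tissue One row of \code{\link{tissue_table}} (or a list with the
#'   same fields).
#' @param seq A \code{\link{sequence_params}}.
#' @return Noiseless signal in arbitrary units, >= 0.
#' @export
mr_signal <- function(tissue, seq) {
  pd <- tissue$proton_density
  if (pd == 0) return(0)
  if (isTRUE(seq$fat_saturation) && isTRUE(tissue$fat_like)) return(0)
  t1 <- tissue$t1; t2 <- tissue$t2
  e1 <- exp(-seq$tr / t1)
  te_decay <- exp(-seq$te / t2)
  s <- switch(seq$kind,
    spin_echo = pd * (1 - e1) * te_decay,
    ute_gre = {
      a <- seq$flip_angle * pi / 180
      pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * te_decay
    },
    inversion_recovery_gre =
      pd * abs(1 - 2 * exp(-seq$ti / t1) + e1) * te_decay
  )
  max(s, 0)
}
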