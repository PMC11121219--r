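#' Fatty-acid family classification
#'
#' The fatty acids quantified in the intramuscular-fat profile, with their
#' saturation family (SFA/MUFA/PUFA) and, for PUFA, the omega family (n-3,
#' n-6, or `other` for trans isomers outside both families).
#'
#' @return Data frame with columns `fa`, `family`, `omega`.
#' @export
fatty_acid_families <- function() {
  sfa <- c("C10:0", "C12:0", "C14:0", "C15:0", "C16:0", "C17:0", "C18:0",
           "C20:0", "C21:0", "C22:0", "C24:0")
  mufa <- c("C14:1", "C15:1", "C16:1n-7", "C17:1n-7", "9t-C18:1",
            "C18:1n-9", "C20:1n-9", "C22:1n-9", "C24:1n-9")
  n6 <- c("C18:2n-6", "C18:3n-6", "C20:2n-6", "C20:3n-6", "C20:4n-6",
          "C22:2n-6")
  n3 <- c("C18:3n-3", "C20:3n-3", "C20:5n-3", "C22:5n-3", "C22:6n-3")
  other_pufa <- "9t,12t-C18:2"
  data.frame(
    fa = c(sfa, mufa, n6, n3, other_pufa),
    family = c(rep("SFA", length(sfa)), rep("MUFA", length(mufa)),
               rep("PUFA", length(n6) + length(n3) + length(other_pufa))),
    omega = c(rep("", length(sfa) + length(mufa)), rep("n-6", length(n6)),
              rep("n-3", length(n3)), rep("other", length(other_pufa))),
    stringsAsFactors = FALSE
  )
}

.fa_value <- function(profile, fa) {
  v <- profile[fa]
  v[is.na(v)] <- 0  # undetected FAs enter the formulas as zero
  unname(v)
}

.as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    stopifnot(nrow(profile) == 1L)
    profile <- unlist(profile[1L, vapply(profile, is.numeric, logical(1L))])
  }
  if (is.null(names(profile)) || !any(nzchar(names(profile))))
    stop("fatty-acid profile must be named by FA (e.g. \"C16:0\")",
         call. = FALSE)
  profile
}

#' Carcass yield
#'
#' Dressing percentage of the chilled carcass: `100 * ccw / lws`, with
#' `ccw` the cold carcass weight and `lws` the live weight at slaughter
#' (both kg). Vectorized.
#'
#' @param ccw Cold carcass weight (kg).
#' @param lws Live weight at slaughter (kg), > 0.
#' @return Yield in percent.
#' @examples
#' carcass_yield(5.8, 10.9)  # 53.2
#' @export
carcass_yield <- function(ccw, lws) {
  if (any(lws <= 0)) stop("'lws' must be positive", call. = FALSE)
  100 * ccw / lws
}

#' CIELab chroma and hue angle
#'
#' Chroma `C* = sqrt(a*^2 + b*^2)` (color saturation) and hue angle
#' `H* = atan(b*/a*)` in degrees. For `a* = 0` with `b* != 0` the limit
#' convention `H* = +/-90` is used. Vectorized.
#'
#' @param a_star Red-green coordinate.
#' @param b_star Yellow-blue coordinate.
#' @return Data frame with columns `C_star` and `H_star` (degrees).
#' @examples
#' chroma_hue(3, 4)  # C* 5, H* 53.13
#' @export
chroma_hue <- function(a_star, b_star) {
  if (any(a_star == 0 & b_star == 0))
    stop("hue undefined at a* = b* = 0", call. = FALSE)
  h <- ifelse(a_star == 0, sign(b_star) * 90,
              atan(b_star / a_star) * 180 / pi)
  data.frame(C_star = sqrt(a_star^2 + b_star^2), H_star = h)
}

#' Fatty-acid family sums and ratios
#'
#' Sums the profile into its SFA, MUFA and PUFA families plus the omega-6
#' and omega-3 PUFA sub-families, and forms the two nutritional ratios
#' n-6/n-3 and PUFA/SFA.
#'
#' @param profile Named numeric vector (or one-row data frame) of
#'   fatty-acid percentages (g FA / 100 g total FA), named as in
#'   [fatty_acid_families()]. Unknown names are ignored with a warning.
#' @return Named numeric vector: `sfa`, `mufa`, `pufa`, `pufa_n6`,
#'   `pufa_n3`, `n6_n3`, `pufa_sfa`.
#' @export
fa_sums_ratios <- function(profile) {
  profile <- .as_profile(profile)
  fam <- fatty_acid_families()
  known <- names(profile) %in% fam$fa
  if (!any(known)) stop("no recognized fatty-acid columns", call. = FALSE)
  if (any(!known))
    warning("ignoring unrecognized profile entries: ",
            paste(names(profile)[!known], collapse = ", "), call. = FALSE)
  p <- profile[known]
  grp <- function(fas) sum(.fa_value(p, fas))
  sfa <- grp(fam$fa[fam$family == "SFA"])
  mufa <- grp(fam$fa[fam$family == "MUFA"])
  pufa <- grp(fam$fa[fam$family == "PUFA"])
  n6 <- grp(fam$fa[fam$omega == "n-6"])
  n3 <- grp(fam$fa[fam$omega == "n-3"])
  if (n3 <= 0) stop("zero omega-3 sum: n-6/n-3 ratio undefined",
                    call. = FALSE)
  if (sfa <= 0) stop("zero SFA sum: PUFA/SFA ratio undefined",
                     call. = FALSE)
  c(sfa = sfa, mufa = mufa, pufa = pufa, pufa_n6 = n6, pufa_n3 = n3,
    n6_n3 = n6 / n3, pufa_sfa = pufa / sfa)
}

#' Lipid nutritional-quality indices
#'
#' The three closed-form indices of lipid healthiness computed from the
#' fatty-acid profile (percentages of total FA):
#'
#' * atherogenicity `IA = (C12:0 + 4 C14:0 + C16:0) / (MUFA + PUFA)`
#' * thrombogenicity `IT = (C14:0 + C16:0 + C18:0) /
#'   (0.5 MUFA + 0.5 n6 + 3 n3 + n3/n6)`
#' * hypocholesterolemic/hypercholesterolemic ratio
#'   `h/H = (C18:1n-9 + C18:2n-6 + C20:4n-6 + C18:3n-3 + C20:5n-3 +
#'   C22:5n-3 + C22:6n-3) / (C14:0 + C16:0)`
#'
#' plus the n-6/n-3 and PUFA/SFA ratios. Fatty acids absent from the
#' profile enter as zero. IA and h/H are ratios of like units and so are
#' invariant to rescaling the whole profile; IT is not (its denominator
#' mixes a percentage scale with the dimensionless n3/n6 term).
#'
#' @inheritParams fa_sums_ratios
#' @param sums Optional named list overriding the family sums used in the
#'   denominators (`mufa`, `pufa`, `pufa_n6`, `pufa_n3`), e.g. when
#'   reproducing a published table whose printed sums include trace FAs
#'   not listed individually.
#' @return Named numeric vector: `ia`, `it`, `h_over_H`, `n6_n3`,
#'   `pufa_sfa`.
#' @export
lipid_indices <- function(profile, sums = NULL) {
  profile <- .as_profile(profile)
  fam <- fatty_acid_families()
  p <- profile[names(profile) %in% fam$fa]
  if (!length(p)) stop("no recognized fatty-acid columns", call. = FALSE)
  grp <- function(fas) sum(.fa_value(p, fas))
  s <- list(sfa = grp(fam$fa[fam$family == "SFA"]),
            mufa = grp(fam$fa[fam$family == "MUFA"]),
            pufa = grp(fam$fa[fam$family == "PUFA"]),
            pufa_n6 = grp(fam$fa[fam$omega == "n-6"]),
            pufa_n3 = grp(fam$fa[fam$omega == "n-3"]))
  for (nm in intersect(names(sums), names(s))) s[[nm]] <- sums[[nm]]
  v <- function(fa) .fa_value(p, fa)

  denom_ia <- s$mufa + s$pufa
  if (denom_ia <= 0) stop("zero MUFA + PUFA: IA undefined", call. = FALSE)
  ia <- (v("C12:0") + 4 * v("C14:0") + v("C16:0")) / denom_ia

  ## the dimensionless n3/n6 term is taken as 0 when no n-3 FAs were
  ## detected; an n-3 presence with zero n-6 leaves IT undefined
  n3_over_n6 <- if (s$pufa_n3 == 0) 0 else {
    if (s$pufa_n6 <= 0)
      stop("omega-3 present with zero omega-6: IT undefined", call. = FALSE)
    s$pufa_n3 / s$pufa_n6
  }
  denom_it <- 0.5 * s$mufa + 0.5 * s$pufa_n6 + 3 * s$pufa_n3 + n3_over_n6
  if (denom_it <= 0) stop("zero denominator: IT undefined", call. = FALSE)
  it <- (v("C14:0") + v("C16:0") + v("C18:0")) / denom_it

  denom_h <- v("C14:0") + v("C16:0")
  h_num <- v("C18:1n-9") + v("C18:2n-6") + v("C20:4n-6") + v("C18:3n-3") +
    v("C20:5n-3") + v("C22:5n-3") + v("C22:6n-3")
  h_over_H <- if (denom_h > 0) h_num / denom_h else {
    warning("zero C14:0 + C16:0: h/H undefined", call. = FALSE)
    NA_real_
  }
  c(ia = ia, it = it, h_over_H = h_over_H,
    n6_n3 = if (s$pufa_n3 > 0) s$pufa_n6 / s$pufa_n3 else NA_real_,
    pufa_sfa = if (s$sfa > 0) s$pufa / s$sfa else NA_real_)
}
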