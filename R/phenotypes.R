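#' Hypertriglyceridemic-waist (HTGW) indicator
#'
#' HTGW is defined as high waist circumference combined with high fasting
#' triglycerides, with sex-specific thresholds (defaults: waist >= 90 cm in
#' males, >= 85 cm in females; triglycerides >= 2.0 mmol/L in males,
#' >= 1.5 mmol/L in females).  Comparisons are inclusive.  A missing waist
#' or triglyceride value yields a missing indicator; the number of missing
#' indicators is attached as attribute \code{n_missing}.
#'
#' @param waist waist circumference in cm
#' @param tg fasting serum triglycerides in mmol/L
#' @param sex 1/\code{"M"} male, 2/\code{"F"} female
#' @param waist_cut,tg_cut named vectors of (male, female) thresholds
#' @return integer 0/1/NA vector
#' @export
make_htgw <- function(waist, tg, sex,
                      waist_cut = c(male = 90, female = 85),
                      tg_cut = c(male = 2.0, female = 1.5)) {
  sex <- normalize_sex(sex)
  wcut <- ifelse(sex == 1L, waist_cut[["male"]], waist_cut[["female"]])
  tcut <- ifelse(sex == 1L, tg_cut[["male"]], tg_cut[["female"]])
  out <- as.integer(waist >= wcut & tg >= tcut)
  out[is.na(waist) | is.na(tg)] <- NA_integer_
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Mutually exclusive HTGW component indicators
#'
#' Splits the samples into four categories by the two sex-specific
#' thresholds of [make_htgw()]: both high (HTGW), waist-only high, TG-only
#' high, with "neither high" as the reference.  The three returned
#' indicator columns are mutually exclusive and, together with the
#' reference, partition the non-missing samples.
#'
#' @inheritParams make_htgw
#' @return integer matrix with columns \code{both_high}, \code{waist_only},
#'   \code{tg_only}
#' @export
component_indicators <- function(waist, tg, sex,
                                 waist_cut = c(male = 90, female = 85),
                                 tg_cut = c(male = 2.0, female = 1.5)) {
  sex <- normalize_sex(sex)
  wcut <- ifelse(sex == 1L, waist_cut[["male"]], waist_cut[["female"]])
  tcut <- ifelse(sex == 1L, tg_cut[["male"]], tg_cut[["female"]])
  hw <- waist >= wcut
  ht <- tg >= tcut
  miss <- is.na(waist) | is.na(tg)
  out <- cbind(both_high = as.integer(hw & ht),
               waist_only = as.integer(hw & !ht),
               tg_only = as.integer(!hw & ht))
  out[miss, ] <- NA_integer_
  out
}

#' Rank-based inverse normal transform
#'
#' Ranks the values (ties receive average ranks), converts ranks to
#' cumulative densities with the symmetric offset \code{(rank - 0.5) / n},
#' and returns the corresponding standard-normal quantiles.  Missing values
#' pass through as \code{NA} and do not affect the ranks of the rest.
#'
#' @param x numeric vector with at least 3 distinct non-missing values
#' @return z-score vector, mean approximately 0 and SD approximately 1
#' @export
inverse_normal <- function(x) {
  ok <- !is.na(x)
  v <- x[ok]
  if (length(v) < 3L) stop("inverse_normal needs >= 3 non-missing values")
  if (length(unique(v)) == 1L) stop("inverse_normal undefined for constant input")
  r <- rank(v, ties.method = "average")
  z <- stats::qnorm((r - 0.5) / length(v))
  out <- rep(NA_real_, length(x))
  out[ok] <- z
  names(out) <- names(x)
  out
}
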