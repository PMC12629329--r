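## OGTT-derived insulin sensitivity / secretion indices and lipid
## derivations.  All inputs are SI (glucose mmol/L, insulin pmol/L, FFA
## umol/L, lipids mmol/L); the conversions the classical formulas need are
## internal:
##   insulin  1 mU/L  = 6.945 pmol/L
##   glucose  1 mmol/L = 18.016 mg/dL

INSULIN_PMOL_PER_MU <- 6.945
GLUCOSE_MGDL_PER_MMOL <- 18.016
OGTT_MINUTES <- c(0, 15, 30, 45, 60, 90, 120)

#' Trapezoidal area under a sampled curve
#'
#' @param times strictly increasing sampling times (minutes).
#' @param values values at those times.
#' @return area in value x minutes.
#' @export
trapezoid_auc <- function(times, values) {
  if (length(times) < 2 || length(times) != length(values))
    stop_mr("need >= 2 (time, value) points", class = "validation_error")
  if (any(diff(times) <= 0))
    stop_mr("times must be strictly increasing", class = "validation_error")
  sum(diff(times) * (head(values, -1) + values[-1]) / 2)
}

#' One subject-visit OGTT record
#'
#' Seven-point oral glucose tolerance test values plus fasting free fatty
#' acids and the lipid panel, as measured on a clinical investigation day.
#'
#' @param glucose glucose (mmol/L) at minutes 0, 15, 30, 45, 60, 90, 120.
#' @param insulin insulin (pmol/L) at the same minutes.
#' @param ffa0 fasting free fatty acids (umol/L), optional.
#' @param tc,tg,hdl fasting total cholesterol, triglycerides, HDL
#'   (mmol/L), optional.
#' @param minutes sampling grid (default the 7-point OGTT grid).
#' @return list of class `ogtt_record`.
#' @export
ogtt_record <- function(glucose, insulin, ffa0 = NA_real_, tc = NA_real_,
                        tg = NA_real_, hdl = NA_real_,
                        minutes = OGTT_MINUTES) {
  if (length(glucose) != length(minutes) || length(insulin) != length(minutes))
    stop_mr("glucose and insulin must match the minute grid (",
            length(minutes), " points)", class = "validation_error")
  if (any(diff(minutes) <= 0))
    stop_mr("minute grid must be strictly increasing",
            class = "validation_error")
  if (any(glucose <= 0) || any(insulin < 0))
    stop_mr("glucose must be > 0 and insulin >= 0",
            class = "validation_error")
  structure(list(minutes = minutes, glucose = glucose, insulin = insulin,
                 ffa0 = ffa0, tc = tc, tg = tg, hdl = hdl),
            class = "ogtt_record")
}

#' Friedewald LDL cholesterol
#'
#' `LDL = TC - TG/2.2 - HDL` (all mmol/L); valid only for TG <= 4.5
#' mmol/L.
#'
#' @param tc,tg,hdl total cholesterol, triglycerides, HDL (mmol/L).
#' @return LDL cholesterol (mmol/L).
#' @export
friedewald_ldl <- function(tc, tg, hdl) {
  if (any(tg > 4.5))
    stop_mr("Friedewald formula invalid for TG > 4.5 mmol/L",
            class = "validity_error")
  tc - tg / 2.2 - hdl
}

#' HOMA-IR
#'
#' Homeostatic model assessment of insulin resistance:
#' `G0 x I0[mU/L] / 22.5` with fasting glucose in mmol/L and fasting
#' insulin converted from pmol/L.
#'
#' @param g0 fasting glucose (mmol/L).
#' @param i0 fasting insulin (pmol/L).
#' @return index (dimensionless).
#' @export
homa_ir <- function(g0, i0) {
  if (any(g0 <= 0) || any(i0 < 0))
    stop_mr("g0 must be > 0 and i0 >= 0", class = "validation_error")
  g0 * (i0 / INSULIN_PMOL_PER_MU) / 22.5
}

#' HOMA of beta-cell function
#'
#' `20 x I0[mU/L] / (G0 - 3.5)`; defined for fasting glucose above
#' 3.5 mmol/L.
#'
#' @inheritParams homa_ir
#' @return index (percent of reference beta-cell function).
#' @export
homa_beta <- function(g0, i0) {
  if (any(g0 <= 3.5))
    stop_mr("HOMA-beta undefined for G0 <= 3.5 mmol/L",
            class = "domain_error")
  20 * (i0 / INSULIN_PMOL_PER_MU) / (g0 - 3.5)
}

ogtt_means <- function(ogtt) {
  span <- diff(range(ogtt$minutes))
  list(g = trapezoid_auc(ogtt$minutes, ogtt$glucose) / span,
       i = trapezoid_auc(ogtt$minutes, ogtt$insulin) / span)
}

#' Matsuda whole-body insulin sensitivity index
#'
#' `10000 / sqrt(G0 x I0 x Gmean x Imean)` with glucose in mg/dL, insulin
#' in mU/L, and the means taken as time-weighted (trapezoidal) OGTT
#' averages.
#'
#' @param ogtt an [ogtt_record()].
#' @return index (dimensionless).
#' @export
matsuda_index <- function(ogtt) {
  mu <- ogtt_means(ogtt)
  g0 <- ogtt$glucose[1] * GLUCOSE_MGDL_PER_MMOL
  i0 <- ogtt$insulin[1] / INSULIN_PMOL_PER_MU
  gm <- mu$g * GLUCOSE_MGDL_PER_MMOL
  im <- mu$i / INSULIN_PMOL_PER_MU
  prod4 <- g0 * i0 * gm * im
  if (prod4 <= 0)
    stop_mr("Matsuda index undefined: zero factor", class = "domain_error")
  10000 / sqrt(prod4)
}

#' Hepatic insulin resistance index
#'
#' `AUC_glucose(0-30) x AUC_insulin(0-30)` with glucose in mg/dL x min and
#' insulin in mU/L x min.
#'
#' @inheritParams matsuda_index
#' @return index.
#' @export
hiri <- function(ogtt) {
  sel <- ogtt$minutes <= 30
  auc_g <- trapezoid_auc(ogtt$minutes[sel],
                         ogtt$glucose[sel] * GLUCOSE_MGDL_PER_MMOL)
  auc_i <- trapezoid_auc(ogtt$minutes[sel],
                         ogtt$insulin[sel] / INSULIN_PMOL_PER_MU)
  auc_g * auc_i
}

#' Muscle insulin sensitivity index
#'
#' Rate of plasma glucose decline from the OGTT peak to the subsequent
#' nadir (linear fit over that segment, mmol/L per minute) divided by the
#' mean OGTT insulin (mU/L, trapezoidal mean).
#'
#' @inheritParams matsuda_index
#' @return index (mmol/L/min per mU/L).
#' @export
misi <- function(ogtt) {
  pk <- which.max(ogtt$glucose)
  if (pk == length(ogtt$glucose))
    stop_mr("MISI undefined: glucose peak at the final sample",
            class = "domain_error")
  nd <- pk - 1 + which.min(ogtt$glucose[pk:length(ogtt$glucose)])
  seg <- pk:nd
  slope <- unname(coef(lm(ogtt$glucose[seg] ~ ogtt$minutes[seg]))[2])
  im <- ogtt_means(ogtt)$i / INSULIN_PMOL_PER_MU
  -slope / im
}

#' Adipose tissue insulin resistance index
#'
#' Fasting FFA (converted to mmol/L) times fasting insulin (pmol/L).
#'
#' @param ffa0 fasting free fatty acids (umol/L).
#' @param i0 fasting insulin (pmol/L).
#' @return index (mmol/L x pmol/L).
#' @export
adipo_ir <- function(ffa0, i0) {
  (ffa0 / 1000) * i0
}

#' Insulinogenic index
#'
#' Early-phase insulin secretion: `(I30 - I0) / (G30 - G0)` in pmol/L per
#' mmol/L.
#'
#' @inheritParams matsuda_index
#' @return index.
#' @export
insulinogenic_index <- function(ogtt) {
  i30 <- ogtt$insulin[ogtt$minutes == 30]
  g30 <- ogtt$glucose[ogtt$minutes == 30]
  if (length(i30) != 1)
    stop_mr("insulinogenic index needs the 30-minute sample",
            class = "validation_error")
  if (g30 == ogtt$glucose[1])
    stop_mr("insulinogenic index undefined: G30 = G0",
            class = "domain_error")
  (i30 - ogtt$insulin[1]) / (g30 - ogtt$glucose[1])
}

#' Disposition index
#'
#' Insulin secretion adjusted for sensitivity: insulinogenic index times
#' the Matsuda index.
#'
#' @inheritParams matsuda_index
#' @return index.
#' @export
disposition_index <- function(ogtt) {
  insulinogenic_index(ogtt) * matsuda_index(ogtt)
}

#' Full metabolic index panel for one OGTT record
#'
#' @inheritParams matsuda_index
#' @return tibble with one row: HOMA-IR, Matsuda, HIRI, MISI, ADIPO-IR
#'   (when FFA present), HOMA-beta, insulinogenic index, disposition
#'   index, and Friedewald LDL (when the lipid panel is present and TG <=
#'   4.5 mmol/L, else `NA`).
#' @export
index_panel <- function(ogtt) {
  stopifnot(inherits(ogtt, "ogtt_record"))
  ldl <- if (any(is.na(c(ogtt$tc, ogtt$tg, ogtt$hdl)))) NA_real_
         else if (ogtt$tg > 4.5) NA_real_
         else friedewald_ldl(ogtt$tc, ogtt$tg, ogtt$hdl)
  tibble::tibble(
    homa_ir = homa_ir(ogtt$glucose[1], ogtt$insulin[1]),
    matsuda = matsuda_index(ogtt),
    hiri = hiri(ogtt),
    misi = misi(ogtt),
    adipo_ir = if (is.na(ogtt$ffa0)) NA_real_
               else adipo_ir(ogtt$ffa0, ogtt$insulin[1]),
    homa_beta = homa_beta(ogtt$glucose[1], ogtt$insulin[1]),
    insulinogenic = insulinogenic_index(ogtt),
    disposition = disposition_index(ogtt),
    ldl = ldl)
}
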