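# ICD-9-CM chapter grouping: every syntactically valid diagnosis code maps to
# exactly one of the 20 top-level groups (19 numeric chapters + V codes SUPP
# + E codes EXT).

#' The 20 ICD-9-CM group labels
#'
#' Canonical ordering of the chapter-group labels used throughout the package
#' (INFE infectious, NEOP neoplastic, META endocrine/metabolic, ..., SUPP
#' supplementary V codes, EXT external-cause E codes).
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' icd9_group_labels()
icd9_group_labels <- function() {
  c("INFE", "NEOP", "META", "BLD", "MENT", "NERV", "SENS", "CIRC", "RESP",
    "DIGE", "GEN", "PREG", "SKIN", "MUSC", "CONG", "NEWB", "ILL", "INJ",
    "SUPP", "EXT")
}

#' Default ICD-9-CM chapter-to-group map
#'
#' Standard ICD-9-CM chapter boundaries: numeric three-digit stems are mapped
#' by inclusive `[lo, hi]` ranges (001-139 INFE, 140-239 NEOP, 240-279 META,
#' 280-289 BLD, 290-319 MENT, 320-359 NERV, 360-389 SENS, 390-459 CIRC,
#' 460-519 RESP, 520-579 DIGE, 580-629 GEN, 630-679 PREG, 680-709 SKIN,
#' 710-739 MUSC, 740-759 CONG, 760-779 NEWB, 780-799 ILL, 800-999 INJ), while
#' V-prefixed codes map to SUPP and E-prefixed codes to EXT. The ranges are
#' disjoint and jointly cover every syntactically valid code.
#'
#' @return A tibble with columns `group`, `prefix` (`""` for numeric chapters,
#'   `"V"` or `"E"` for the prefix rules), `lo`, `hi` (integer stem bounds,
#'   `NA` for prefix rules) and `description`.
#' @export
#' @examples
#' default_group_map()
default_group_map <- function() {
  tibble(
    group = icd9_group_labels(),
    prefix = c(rep("", 18L), "V", "E"),
    lo = c(1L, 140L, 240L, 280L, 290L, 320L, 360L, 390L, 460L, 520L, 580L,
           630L, 680L, 710L, 740L, 760L, 780L, 800L, NA, NA),
    hi = c(139L, 239L, 279L, 289L, 319L, 359L, 389L, 459L, 519L, 579L, 629L,
           679L, 709L, 739L, 759L, 779L, 799L, 999L, NA, NA),
    description = c(
      "infectious and parasitic diseases", "neoplasms",
      "endocrine, nutritional, metabolic, immunity",
      "blood and blood-forming organs", "mental disorders",
      "nervous system", "sense organs", "circulatory system",
      "respiratory system", "digestive system", "genitourinary system",
      "pregnancy, childbirth, puerperium", "skin and subcutaneous tissue",
      "musculoskeletal system and connective tissue", "congenital anomalies",
      "perinatal conditions", "symptoms, signs, ill-defined conditions",
      "injury and poisoning", "supplementary factors (V codes)",
      "external causes (E codes)")
  )
}

#' Check ICD-9-CM code syntax
#'
#' A valid code is `ddd`, `ddd.d`, `ddd.dd`, `Vdd` (optionally `.d`/`.dd`)
#' or `Eddd` (optionally `.d`).
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector.
#' @export
#' @examples
#' icd9_valid(c("401", "250.42", "V70.0", "E880.9", "XYZ"))
icd9_valid <- function(code) {
  stringr::str_detect(
    code,
    "^(\\d{3}(\\.\\d{1,2})?|V\\d{2}(\\.\\d{1,2})?|E\\d{3}(\\.\\d)?)$"
  ) & !is.na(code)
}

#' Map ICD-9-CM codes to chapter groups
#'
#' Sub-codes map with their three-digit stem (250.42 maps with 250, to META).
#'
#' @param code Character vector of syntactically valid codes.
#' @param group_map Mapping table, as from [default_group_map()].
#' @return Character vector of group labels, same length as `code`.
#' @export
#' @examples
#' map_code_to_group(c("401", "250.42", "V10"))
map_code_to_group <- function(code, group_map = default_group_map()) {
  ok <- icd9_valid(code)
  if (any(!ok)) {
    abort(paste0("unmappable ICD-9-CM code(s): ",
                 paste(unique(code[!ok]), collapse = ", ")))
  }
  stem <- sub("\\..*$", "", code)
  out <- character(length(code))

  is_v <- startsWith(stem, "V")
  is_e <- startsWith(stem, "E")
  out[is_v] <- group_map$group[match("V", group_map$prefix)]
  out[is_e] <- group_map$group[match("E", group_map$prefix)]

  num <- !is_v & !is_e
  if (any(num)) {
    ranges <- group_map[group_map$prefix == "", ]
    ranges <- ranges[order(ranges$lo), ]
    stem_num <- as.integer(stem[num])
    idx <- findInterval(stem_num, ranges$lo)
    bad <- idx == 0L | stem_num > ranges$hi[pmax(idx, 1L)]
    if (any(bad)) {
      abort(paste0("ICD-9-CM stem(s) not covered by the group map: ",
                   paste(unique(stem_num[bad]), collapse = ", ")))
    }
    out[num] <- ranges$group[idx]
  }
  out
}

# Representative codes per group, used by the synthetic generator so that the
# mapper is exercised with realistic codes. Downstream analyses only see the
# group label.
group_example_codes <- function() {
  list(
    INFE = c("008.8", "034.0", "079.99"),
    NEOP = c("174.9", "185", "208.91"),
    # no 250.x here: diabetes codes are attached only to diabetic patients'
    # drug prescriptions by the generator (see diabetes_codes())
    META = c("272.0", "244.9", "255.8"),
    BLD  = c("280.9", "285.9"),
    MENT = c("300.00", "311"),
    NERV = c("345.90", "356.9"),
    SENS = c("366.9", "389.10"),
    CIRC = c("401.9", "414.00", "427.31"),
    RESP = c("466.0", "493.90"),
    DIGE = c("530.81", "535.50"),
    GEN  = c("599.0", "600.00"),
    PREG = c("650"),
    SKIN = c("692.9", "706.1"),
    MUSC = c("715.90", "724.2"),
    CONG = c("745.5"),
    NEWB = c("765.10"),
    ILL  = c("780.79", "786.50"),
    INJ  = c("845.00", "959.9"),
    SUPP = c("V70.0", "V04.81"),
    EXT  = c("E880.9")
  )
}

# Diabetes diagnosis codes (ICD-9 250.00-250.99): the ones the generator
# attaches to diabetic patients' drug prescriptions.
diabetes_codes <- function() c("250.00", "250.01", "250.02", "250.40")
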