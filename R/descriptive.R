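# Descriptive summaries of power-vector panels and device/time differences.

#' Summary statistics for one power-vector component
#'
#' Arithmetic mean, standard deviation (n-1 denominator), median and the
#' empirical 2.5th / 97.5th percentiles (linear-interpolation quantiles,
#' `type = 7`), the bounds conventionally reported as the 95% confidence
#' interval of the distribution.
#'
#' @param values numeric vector (finite).
#' @param na_rm drop missing values before summarising.
#' @return named numeric vector `mean`, `sd`, `median`, `p2.5`, `p97.5`, `n`.
#' @export
component_summary <- function(values, na_rm = FALSE) {
  if (na_rm) values <- values[!is.na(values)]
  if (length(values) == 0) stop_invalid("cannot summarise an empty vector")
  check_numeric(values, "values")
  q <- stats::quantile(values, c(0.025, 0.975), type = 7, names = FALSE)
  c(mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
    median = stats::median(values),
    p2.5 = q[1], p97.5 = q[2],
    n = length(values))
}

#' Summarise every (device, layer, component) of a panel
#'
#' @param panel decomposed panel from [decompose_cohort()].
#' @return long data frame with one row per device x layer x component and
#'   columns `mean`, `sd`, `median`, `p2.5`, `p97.5`, `n`.
#' @export
summarize_panel <- function(panel) {
  value_cols <- setdiff(names(panel), c("patient_id", "eye", "mirrored"))
  out <- do.call(rbind, lapply(value_cols, function(cc) {
    parts <- strsplit(cc, "_")[[1]]
    comp <- parts[length(parts)]
    layer <- parts[length(parts) - 1]
    device <- paste(parts[seq_len(length(parts) - 2)], collapse = "_")
    s <- component_summary(panel[[cc]])
    data.frame(device = device, layer = layer, component = comp,
               t(s), stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-eye power-vector differences between two panels
#'
#' Subtracts panel `b` from panel `a` componentwise per eye (matched on
#' `patient_id`) and summarises each difference component; this is the
#' device-comparison / surgically-induced-astigmatism table.  `a` and `b`
#' may be the same panel restricted to different devices via `device_a` /
#' `device_b`, which is the common use.
#'
#' @param a,b decomposed panels covering identical eye sets.
#' @param device_a,device_b device whose layers are differenced
#'   (`a[device_a] - b[device_b]`).
#' @return list with `differences` (per-eye data frame of
#'   `<layer>_<component>` differences) and `summary` (long data frame as in
#'   [summarize_panel()], with a `contrast` column).
#' @export
difference_panel <- function(a, b, device_a = "CASIA_post", device_b = "IOLM") {
  if (nrow(a) != nrow(b) || !setequal(a$patient_id, b$patient_id))
    stop_invalid("panels cover different eye sets (e.g. %s)",
                 paste(utils::head(c(setdiff(a$patient_id, b$patient_id),
                                     setdiff(b$patient_id, a$patient_id)), 3),
                       collapse = ", "))
  b <- b[match(a$patient_id, b$patient_id), , drop = FALSE]
  diffs <- data.frame(patient_id = a$patient_id, eye = a$eye,
                      stringsAsFactors = FALSE)
  for (layer in panel_layers) {
    d <- pv_subtract(panel_block(a, device_a, layer),
                     panel_block(b, device_b, layer))
    for (comp in colnames(d))
      diffs[[paste(layer, comp, sep = "_")]] <- d[, comp]
  }
  value_cols <- setdiff(names(diffs), c("patient_id", "eye"))
  summ <- do.call(rbind, lapply(value_cols, function(cc) {
    parts <- strsplit(cc, "_")[[1]]
    s <- component_summary(diffs[[cc]])
    data.frame(contrast = paste(device_a, "-", device_b),
               layer = parts[1], component = parts[2],
               t(s), stringsAsFactors = FALSE, check.names = FALSE)
  }))
  rownames(summ) <- NULL
  list(differences = diffs, summary = summ)
}

#' Ratio of mean equivalent powers between two corneal layers
#'
#' The front/back mean-EQ ratio diagnoses how a device's back-surface power
#' relates to the fixed front-to-back ratio assumed by a keratometer index
#' (-7.7426 for the Liou-Brennan schematic eye).
#'
#' @param panel decomposed panel, or a named numeric vector of mean EQ values
#'   per layer (e.g. `c(front = 48.5266, back = -5.7897)`).
#' @param device device to use when `panel` is a panel data frame.
#' @param layer_a,layer_b numerator and denominator layers.
#' @return the dimensionless ratio of mean EQ values.
#' @export
ratio_of_mean_powers <- function(panel, device = "IOLM",
                                 layer_a = "front", layer_b = "back") {
  if (is.numeric(panel) && !is.null(names(panel))) {
    num <- panel[[layer_a]]
    den <- panel[[layer_b]]
  } else {
    num <- mean(panel_block(panel, device, layer_a, "EQ"))
    den <- mean(panel_block(panel, device, layer_b, "EQ"))
  }
  if (!is.finite(den) || den == 0)
    stop_invalid("mean EQ of layer '%s' is zero or non-finite", layer_b)
  num / den
}
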