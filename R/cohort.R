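# Cohort CSV input, exclusion rules, and decomposition into power-vector
# panels.
#
# The expected CSV carries one eye per row with the measurement vocabulary of
# the two devices: IOLMaster 700 biometry ("IOLM", preoperative) and Casia2
# anterior-segment OCT ("CASIA", pre- and postoperative), each providing
# front surface, back surface and a composite (total keratometry for the
# IOLM, real power for the CASIA) measurement.

iolm_surface_cols <- function(code) paste0("IOLM", c("R1", "A1", "R2", "A2"), code)
casia_surface_cols <- function(code, when) paste0("CASIA", c("R1", "A1", "R2", "A2"), code, "_", when)
casia_real_cols <- function(when) paste0("CASIA", c("P1", "A1", "P2", "A2"), "r_", when)

#' Canonical cohort CSV columns
#'
#' @return a list with character vectors `mandatory`, `optional` and
#'   `numeric` naming the canonical column vocabulary of the per-eye CSV.
#' @export
cohort_columns <- function() {
  meas <- c(iolm_surface_cols("a"), iolm_surface_cols("p"), iolm_surface_cols("t"),
            casia_surface_cols("a", "pre"), casia_surface_cols("p", "pre"),
            casia_real_cols("pre"),
            casia_surface_cols("a", "post"), casia_surface_cols("p", "post"),
            casia_real_cols("post"))
  mandatory <- c("patient_id", "eye", "AL", "CCT", "ACD", "LT",
                 "pupil_pre", "pupil_post",
                 "IOLM_quality", "CASIA_pre_quality", "CASIA_post_quality",
                 meas)
  optional <- c("age", "IOLP", "IOLT", "IOLA", "REFS", "REFC", "REFA")
  numeric <- setdiff(c(mandatory, optional),
                     c("patient_id", "eye",
                       "IOLM_quality", "CASIA_pre_quality", "CASIA_post_quality"))
  list(mandatory = mandatory, optional = optional, numeric = numeric,
       measurement = meas)
}

#' Read a per-eye cohort CSV
#'
#' Reads a comma-separated file (header row, decimal point) with one eye per
#' row.  Column names may be remapped through `column_map`; unparseable
#' numeric cells become `NA`, never silent zeros.
#'
#' @param path path to the CSV file.
#' @param column_map optional named character vector mapping canonical names
#'   (see [cohort_columns()]) to the file's column names, e.g.
#'   `c(patient_id = "ID")`.
#' @return a data frame of eye records in canonical columns.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      fcol <- column_map[[canon]]
      if (!fcol %in% names(raw))
        stop_invalid("column map names '%s' which is absent from the file", fcol)
      names(raw)[names(raw) == fcol] <- canon
    }
  }
  cols <- cohort_columns()
  absent <- setdiff(cols$mandatory, names(raw))
  if (length(absent))
    stop_invalid("cohort CSV is missing mandatory column(s): %s",
                 paste(absent, collapse = ", "))
  for (cc in intersect(cols$numeric, names(raw)))
    raw[[cc]] <- suppressWarnings(as.numeric(raw[[cc]]))
  raw$patient_id <- as.character(raw$patient_id)
  raw$eye <- toupper(as.character(raw$eye))
  bad_eye <- !raw$eye %in% c("OD", "OS")
  if (any(bad_eye))
    stop_invalid("eye must be OD or OS (offending rows: %s)",
                 paste(utils::head(which(bad_eye), 5), collapse = ", "))
  raw
}

#' Write a cohort back to CSV
#'
#' @param records data frame of eye records.
#' @param path output path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

flagged <- function(x) {
  tolower(trimws(as.character(x))) %in% c("failed", "warning")
}

#' Apply the cohort exclusion rules
#'
#' Drops records with (i) a "Failed" or "Warning" quality flag (matched
#' case-insensitively; all other strings pass) on any measurement group,
#' (ii) missing measurement, biometry (AL, CCT, ACD, LT) or pupil values,
#' (iii) mydriatic pupils (strictly `> 5.5` mm pre- or postoperatively) or a
#' pre-to-post pupil change strictly `> 1.5` mm, and finally (iv) retains
#' exactly one randomly chosen eye per patient.  The one-eye draw uses its
#' own seed so it is reproducible independently of any later train/test
#' split.
#'
#' @param records data frame from [read_cohort_csv()] (or
#'   [generate_cohort()]).
#' @param seed integer seed for the one-eye-per-patient draw.
#' @return a list with `retained` (data frame) and `excluded` (data frame
#'   with `patient_id`, `eye`, `reason`).
#' @export
apply_exclusions <- function(records, seed = 1) {
  cols <- cohort_columns()
  n <- nrow(records)
  reasons <- vector("list", n)
  add_reason <- function(idx, msg) {
    for (i in which(idx)) reasons[[i]] <<- c(reasons[[i]], msg)
  }
  for (grp in c("IOLM_quality", "CASIA_pre_quality", "CASIA_post_quality"))
    add_reason(flagged(records[[grp]]), paste0("quality flag (", grp, ")"))
  required_num <- c("AL", "CCT", "ACD", "LT", "pupil_pre", "pupil_post",
                    cols$measurement)
  for (cc in required_num)
    add_reason(is.na(records[[cc]]), paste0("missing ", cc))
  ok_pupil <- !is.na(records$pupil_pre) & !is.na(records$pupil_post)
  add_reason(ok_pupil & records$pupil_pre > 5.5, "mydriasis at preoperative measurement (pupil > 5.5 mm)")
  add_reason(ok_pupil & records$pupil_post > 5.5, "mydriasis at postoperative measurement (pupil > 5.5 mm)")
  add_reason(ok_pupil & abs(records$pupil_post - records$pupil_pre) > 1.5,
             "pupil size change > 1.5 mm")
  drop <- !vapply(reasons, is.null, logical(1))

  # one eye per patient among the survivors, seeded draw
  keep <- which(!drop)
  if (length(keep)) {
    by_pat <- split(keep, records$patient_id[keep])
    chosen <- with_local_seed(seed, {
      unlist(lapply(by_pat, function(ix) {
        if (length(ix) == 1) ix else ix[sample.int(length(ix), 1)]
      }), use.names = FALSE)
    })
    fellow <- setdiff(keep, chosen)
    add_reason(seq_len(n) %in% fellow, "fellow eye of an included patient")
    drop <- !vapply(reasons, is.null, logical(1))
  }

  excluded <- data.frame(
    patient_id = records$patient_id[drop],
    eye = records$eye[drop],
    reason = vapply(reasons[drop], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  list(retained = records[!drop, , drop = FALSE], excluded = excluded)
}

panel_devices <- c("IOLM", "CASIA_pre", "CASIA_post")
panel_layers <- c("front", "back", "keratometric", "total")

#' Decompose a cohort into a power-vector panel
#'
#' Converts every retained eye's measurements into power vectors: front and
#' back surfaces with the Liou-Brennan index steps (+0.376 / -0.040),
#' keratometry and IOLM total keratometry with the keratometer index
#' (+0.332), and CASIA real power directly from its meridional powers.  The
#' C45 component of every vector is sign-reversed for left (OS) eyes so the
#' panel is in right-eye orientation throughout.
#'
#' @param records data frame of retained eye records.
#' @return a data frame with `patient_id`, `eye`, `mirrored`, and numeric
#'   columns `<device>_<layer>_<component>` for device in
#'   `IOLM`/`CASIA_pre`/`CASIA_post`, layer in
#'   `front`/`back`/`keratometric`/`total` and component in `EQ`/`C0`/`C45`.
#'   The `total` layer is total keratometry for the IOLM and real power for
#'   the CASIA.
#' @export
decompose_cohort <- function(records) {
  os <- records$eye == "OS"
  panel <- data.frame(patient_id = records$patient_id,
                      eye = records$eye,
                      mirrored = os,
                      stringsAsFactors = FALSE)
  put <- function(device, layer, pv) {
    pv[os, ] <- mirror_for_left_eye(pv[os, , drop = FALSE])
    for (comp in colnames(pv))
      panel[[paste(device, layer, comp, sep = "_")]] <<- pv[, comp]
  }
  dec_surface <- function(cols, media) {
    tryCatch(
      radii_to_power_vector(records[[cols[1]]], records[[cols[2]]],
                            records[[cols[3]]], media),
      error = function(e) stop_invalid("decomposition failed (%s): %s",
                                       cols[1], conditionMessage(e)))
  }
  put("IOLM", "front", dec_surface(iolm_surface_cols("a"), "front"))
  put("IOLM", "back", dec_surface(iolm_surface_cols("p"), "back"))
  put("IOLM", "keratometric", dec_surface(iolm_surface_cols("a"), "keratometric"))
  put("IOLM", "total", dec_surface(iolm_surface_cols("t"), "keratometric"))
  for (when in c("pre", "post")) {
    dev <- paste0("CASIA_", when)
    put(dev, "front", dec_surface(casia_surface_cols("a", when), "front"))
    put(dev, "back", dec_surface(casia_surface_cols("p", when), "back"))
    put(dev, "keratometric", dec_surface(casia_surface_cols("a", when), "keratometric"))
    rc <- casia_real_cols(when)
    put(dev, "total",
        powers_to_power_vector(records[[rc[1]]], records[[rc[2]]],
                               records[[rc[3]]]))
  }
  panel
}

#' Extract a (C0, C45) or (EQ, C0, C45) block from a panel
#'
#' @param panel a decomposed panel from [decompose_cohort()].
#' @param device one of `"IOLM"`, `"CASIA_pre"`, `"CASIA_post"`.
#' @param layer one of `"front"`, `"back"`, `"keratometric"`, `"total"`.
#' @param components which components to extract.
#' @return numeric matrix with the requested components.
#' @export
panel_block <- function(panel, device, layer,
                        components = c("EQ", "C0", "C45")) {
  device <- match.arg(device, panel_devices)
  layer <- match.arg(layer, panel_layers)
  cols <- paste(device, layer, components, sep = "_")
  absent <- setdiff(cols, names(panel))
  if (length(absent))
    stop_invalid("panel lacks column(s): %s", paste(absent, collapse = ", "))
  m <- as.matrix(panel[, cols, drop = FALSE])
  colnames(m) <- components
  m
}
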