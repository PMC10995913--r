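# Readers/writers for participant ROI tables and FreeSurfer stats files.

.covariate_cols <- c("participant_id", "age", "sex", "site", "group")

#' Write a cohort table to CSV
#'
#' Column order: participant_id, age, sex, site, group, any clinical
#' columns, then the region columns in canonical index order.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @param index Region index.
#' @export
write_cohort_csv <- function(cohort, path, index = region_index()) {
  regions <- intersect(index$name, names(cohort))
  clinical <- setdiff(names(cohort), c(.covariate_cols, index$name))
  cohort <- cohort[, c(.covariate_cols, clinical, regions)]
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a participant ROI table
#'
#' Reads a CSV/TSV with one row per participant: id, age, sex, site, group,
#' optional clinical columns, and the 169 region columns. Region columns
#' are validated against the canonical index and reordered to canonical
#' order; missing regions, non-numeric region values and duplicate ids are
#' reported explicitly.
#'
#' @param path Input file (delimiter inferred from the extension: `.tsv`
#'   reads tab-separated, anything else comma-separated).
#' @param index Region index to validate against.
#' @return A cohort data frame in canonical column order.
#' @export
read_roi_table <- function(path, index = region_index()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cov <- setdiff(setdiff(.covariate_cols, "group"), names(tab))
  if (length(missing_cov))
    stop("validation error: missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  if (!"group" %in% names(tab)) tab$group <- "unknown"
  missing_reg <- setdiff(index$name, names(tab))
  if (length(missing_reg))
    stop("validation error: missing region column(s): ",
         paste(utils::head(missing_reg, 10), collapse = ", "),
         if (length(missing_reg) > 10) sprintf(" (+%d more)", length(missing_reg) - 10),
         call. = FALSE)
  bad <- index$name[!vapply(tab[index$name], is.numeric, logical(1))]
  if (length(bad))
    stop("validation error: non-numeric region column(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  dup <- unique(tab$participant_id[duplicated(tab$participant_id)])
  if (length(dup))
    stop("validation error: duplicate participant id(s): ",
         paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  clinical <- setdiff(names(tab), c(.covariate_cols, index$name))
  tab[, c(.covariate_cols, clinical, index$name)]
}

# map a stats-file struct name to the canonical index name
.map_fs_label <- function(label, hemi, kind, index) {
  name <- if (kind == "cortical_thickness")
    paste0(if (hemi == "lh") "lh_" else "rh_", label) else label
  if (!name %in% index$name) return(NA_character_)
  name
}

# parse one FreeSurfer stats file into a named vector of values
.parse_fs_stats <- function(path, value_col) {
  lines <- readLines(path, warn = FALSE)
  header_line <- grep("^# ColHeaders", lines)
  if (length(header_line) != 1L)
    stop("parse error in ", basename(path),
         ": no '# ColHeaders' line found", call. = FALSE)
  headers <- strsplit(sub("^# ColHeaders\\s+", "", lines[header_line]),
                      "\\s+")[[1]]
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (!length(body_idx))
    stop("parse error in ", basename(path), ": no table rows", call. = FALSE)
  if (!value_col %in% headers)
    stop("parse error in ", basename(path), ": no '", value_col,
         "' column (line ", header_line, ")", call. = FALSE)
  name_col <- if ("StructName" %in% headers) "StructName" else headers[1]
  vals <- stats::setNames(numeric(length(body_idx)), rep("", length(body_idx)))
  for (k in seq_along(body_idx)) {
    i <- body_idx[k]
    fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(fields) != length(headers))
      stop("parse error in ", basename(path), " at line ", i, ": expected ",
           length(headers), " fields, found ", length(fields), call. = FALSE)
    v <- suppressWarnings(as.numeric(fields[match(value_col, headers)]))
    if (is.na(v))
      stop("parse error in ", basename(path), " at line ", i,
           ": non-numeric '", value_col, "' value", call. = FALSE)
    vals[k] <- v
    names(vals)[k] <- fields[match(name_col, headers)]
  }
  vals
}

#' Read one participant from FreeSurfer stats files
#'
#' Parses the FreeSurfer stats dialect (`#`-comment headers, a
#' `# ColHeaders` line, whitespace-delimited table): `ThickAvg` from the
#' two `?h.aparc.a2009s.stats` files for the 148 cortical thicknesses and
#' `Volume_mm3` from `aseg.stats` for the 21 subcortical volumes. Labels
#' are mapped onto the canonical region index; labels outside the index are
#' an error for cortical files and silently skipped for aseg (which lists
#' many more structures than the 21 used here).
#'
#' @param lh_aparc,rh_aparc,aseg Paths to the three stats files.
#' @param participant_id,age,sex,site,group Covariates for the row.
#' @param index Region index.
#' @return A one-row cohort data frame.
#' @export
read_freesurfer_stats <- function(lh_aparc, rh_aparc, aseg,
                                  participant_id, age, sex, site,
                                  group = "unknown", index = region_index()) {
  row <- stats::setNames(rep(NA_real_, nrow(index)), index$name)
  for (h in c("lh", "rh")) {
    path <- if (h == "lh") lh_aparc else rh_aparc
    vals <- .parse_fs_stats(path, "ThickAvg")
    mapped <- paste0(h, "_", names(vals))
    unknown <- setdiff(mapped, index$name)
    if (length(unknown))
      stop("parse error in ", basename(path), ": unknown label(s): ",
           paste(sub(paste0("^", h, "_"), "", utils::head(unknown, 5)),
                 collapse = ", "), call. = FALSE)
    row[mapped] <- vals
  }
  aseg_vals <- .parse_fs_stats(aseg, "Volume_mm3")
  keep <- intersect(names(aseg_vals), index$name)
  row[keep] <- aseg_vals[keep]
  missing <- names(row)[is.na(row)]
  if (length(missing))
    stop("stats files do not cover region(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  cbind(data.frame(participant_id = participant_id, age = age, sex = sex,
                   site = site, group = group, stringsAsFactors = FALSE),
        as.data.frame(as.list(row), check.names = FALSE))
}
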