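## Cohort table reading/writing.  All residue and transcript positions are
## 1-based inclusive throughout.

.REQUIRED_COHORT_COLS <- c("tumor_id", "cancer_type", "tmb", "msi_status")

.readTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"", comment.char = "")
  if (!nrow(d)) stop("empty cohort file: ", path)
  d
}

.parseCodingChange <- function(x) {
  # "c.857C>A" style; returns list(cdna_pos, ref_base, alt_base) or NULLs
  g <- regmatches(x, regexec("^c\\.(\\d+)([ACGTacgt])>([ACGTacgt])$",
                             trimws(x)))[[1]]
  if (!length(g)) return(list(cdna_pos = NA_integer_,
                              ref_base = NA_character_,
                              alt_base = NA_character_))
  list(cdna_pos = as.integer(g[2]), ref_base = toupper(g[3]),
       alt_base = toupper(g[4]))
}

#' Read a cohort table
#'
#' TSV or CSV (delimiter sniffed from the header line) with one row per
#' tumor.  Required columns: `tumor_id`, `cancer_type`, `tmb`,
#' `msi_status`.  Optional: `age`, `sex`, `pole_variants`
#' (semicolon-separated protein labels), `coding_changes`
#' (semicolon-separated `c.857C>A`-style entries aligned with
#' `pole_variants`; blank entries allowed).  Rows whose variants fail to
#' parse, or with invalid TMB, are collected into the rejects table --
#' never silently dropped.
#'
#' @param path Path to the file.
#' @param catalog Driver catalog used to flag drivers; default
#'   [defaultDriverCatalog()].
#' @return A [PoleCohort-class]; rejected rows are available via
#'   [cohortRejects()].
#' @export
readCohort <- function(path, catalog = defaultDriverCatalog()) {
  d <- .readTable(path)
  missing <- setdiff(.REQUIRED_COHORT_COLS, colnames(d))
  if (length(missing))
    stop("cohort file lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (found: ", paste(colnames(d), collapse = ", "), ")")
  if (!"pole_variants" %in% colnames(d))
    stop("cohort file lacks required column(s): pole_variants")
  profiles <- list(); variants <- list(); rejects <- list()
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    res <- tryCatch({
      tmb <- suppressWarnings(as.numeric(row$tmb))
      if (is.na(tmb) || tmb < 0) stop("invalid TMB '", row$tmb, "'")
      labs <- trimws(strsplit(as.character(row$pole_variants), ";")[[1]])
      labs <- labs[nzchar(labs)]
      if (!length(labs)) stop("no POLE variants; profile not in cohort")
      v <- as.data.frame(parsePoleVariants(labs))
      cc <- rep("", length(labs))
      if ("coding_changes" %in% colnames(d) &&
          nzchar(trimws(as.character(row$coding_changes)))) {
        cc0 <- trimws(strsplit(as.character(row$coding_changes),
                               ";")[[1]])
        cc[seq_along(cc0)] <- cc0
      }
      parsedCc <- lapply(cc, .parseCodingChange)
      v$cdna_pos <- vapply(parsedCc, `[[`, 1L, "cdna_pos")
      v$ref_base <- vapply(parsedCc, `[[`, "", "ref_base")
      v$alt_base <- vapply(parsedCc, `[[`, "", "alt_base")
      list(profile = data.frame(
             tumor_id = as.character(row$tumor_id),
             cancer_type = as.character(row$cancer_type),
             tmb = tmb,
             msi_status = as.character(row$msi_status),
             age = if ("age" %in% colnames(d))
               suppressWarnings(as.numeric(row$age)) else NA_real_,
             sex = if ("sex" %in% colnames(d))
               as.character(row$sex) else "unknown",
             stringsAsFactors = FALSE),
           variants = cbind(tumor_id = as.character(row$tumor_id), v,
                            stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects[[length(rejects) + 1L]] <- data.frame(
        row = i, tumor_id = as.character(row$tumor_id),
        reason = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      profiles[[length(profiles) + 1L]] <- res$profile
      variants[[length(variants) + 1L]] <- res$variants
    }
  }
  if (!length(profiles))
    stop("no valid rows in cohort file: ", path)
  vars <- flagDrivers(S4Vectors::DataFrame(do.call(rbind, variants)),
                      catalog)
  PoleCohort(do.call(rbind, profiles), vars,
             rejects = if (length(rejects)) do.call(rbind, rejects)
                       else S4Vectors::DataFrame())
}

#' Write a cohort to the TSV schema readCohort() consumes
#'
#' One row per tumor; variant labels are serialized with
#' [formatPoleVariant()] (semicolon-separated) and coding changes as
#' `c.<pos><ref>><alt>` aligned with the labels (blank for variants
#' without coding-level information).  `writeCohort` then `readCohort`
#' round-trips the cohort.
#'
#' @param cohort A [PoleCohort-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  p <- as.data.frame(tumorProfiles(cohort))
  v <- as.data.frame(poleVariants(cohort))
  lab <- formatPoleVariant(v)
  cc <- ifelse(is.na(v$cdna_pos), "",
               paste0("c.", v$cdna_pos, v$ref_base, ">", v$alt_base))
  p$pole_variants <- vapply(p$tumor_id, function(id)
    paste(lab[v$tumor_id == id], collapse = ";"), "")
  p$coding_changes <- vapply(p$tumor_id, function(id)
    paste(cc[v$tumor_id == id], collapse = ";"), "")
  utils::write.table(p, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
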