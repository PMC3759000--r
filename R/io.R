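#' Read one subject's component-timecourse matrix
#'
#' Reads a whitespace-delimited numeric table (one row per timepoint, one
#' column per component — the mixing-matrix dialect written by ICA tools,
#' conventionally named `<id>_melodic_mix*`).  The subject identifier is
#' parsed from the filename prefix before `"_melodic_mix"`.
#'
#' @param path file path.
#' @return An `fnc_subject` (with `group = NA`).
#' @export
read_timecourse_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  nf <- count.fields(path)
  nf <- nf[!is.na(nf) & nf > 0]
  if (length(nf) == 0)
    stop(sprintf("empty timecourse file: %s", path), call. = FALSE)
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged timecourse file %s: row %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]), call. = FALSE)
  }
  values <- tryCatch(
    as.matrix(read.table(path, header = FALSE,
                         colClasses = "numeric")),
    error = function(e)
      stop(sprintf("non-numeric token in %s: %s", path,
                   conditionMessage(e)), call. = FALSE))
  if (ncol(values) < 3)
    stop(sprintf("%s has %d component column(s); need at least 3",
                 path, ncol(values)), call. = FALSE)
  dimnames(values) <- NULL
  id <- sub("_melodic_mix.*$", "", basename(path))
  structure(list(subject_id = id, values = values, group = NA_character_),
            class = "fnc_subject")
}

#' Write one subject's timecourses in the melodic_mix dialect
#'
#' @param subject an `fnc_subject`.
#' @param dir output directory (created if needed).
#' @return The written path, invisibly.
#' @export
write_timecourse_matrix <- function(subject, dir) {
  stopifnot(inherits(subject, "fnc_subject"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(subject$subject_id, "_melodic_mix_new"))
  # %.17g round-trips doubles exactly through text
  txt <- matrix(sprintf("%.17g", subject$values), nrow = nrow(subject$values))
  write.table(txt, path, row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Comma-separated table with a header; records are returned sorted by
#' subject identifier and `"Disenrolled"` rows are flagged for downstream
#' exclusion (they remain in the table).
#'
#' @param path CSV path.
#' @param diagnosis_field name or index of the diagnosis column.
#' @param id_field name or index of the subject-id column; default the
#'   first column.
#' @return data.frame with columns `subject_id`, `diagnosis`, `excluded`.
#' @export
read_phenotypes <- function(path, diagnosis_field = "diagnosis",
                            id_field = 1L) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(field, what) {
    if (is.numeric(field)) {
      if (field > ncol(tab))
        stop(sprintf("%s column %d out of range", what, field),
             call. = FALSE)
      tab[[field]]
    } else {
      if (!field %in% names(tab))
        stop(sprintf("missing %s column '%s' in %s", what, field, path),
             call. = FALSE)
      tab[[field]]
    }
  }
  ids <- as.character(pick(id_field, "subject-id"))
  diag <- as.character(pick(diagnosis_field, "diagnosis"))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate subject ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  ord <- order(ids)
  data.frame(subject_id = ids[ord], diagnosis = diag[ord],
             excluded = diag[ord] == "Disenrolled",
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' One `<id>_melodic_mix_new` file per subject plus `phenotype.csv`
#' (columns `subject_id`, `diagnosis`).
#'
#' @param cohort an `fnc_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fnc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) write_timecourse_matrix(s, dir)
  write.csv(cohort$phenotype, file.path(dir, "phenotype.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' Discovers timecourse files matching `pattern`, reads the phenotype
#' table, and joins the two by explicit subject id (never by file
#' position).  Subjects present on only one side are reported: by
#' default a warning with the reconciliation listing, upgraded to an
#' error with `strict = TRUE`.
#'
#' @param dir directory of timecourse files.
#' @param phenotype_path phenotype CSV; default `dir/phenotype.csv`.
#' @param diagnosis_field passed to [read_phenotypes()].
#' @param pattern filename pattern for timecourse files.
#' @param strict error (rather than warn) on unmatched subjects.
#' @return An `fnc_cohort` containing the matched subjects (sorted by
#'   id), with attribute `unmatched` = list(files, phenotype).
#' @export
read_cohort <- function(dir, phenotype_path = file.path(dir, "phenotype.csv"),
                        diagnosis_field = "diagnosis",
                        pattern = "melodic_mix", strict = FALSE) {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no timecourse files matching '%s' in %s", pattern, dir),
         call. = FALSE)
  subjects <- lapply(files, read_timecourse_matrix)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  pheno <- read_phenotypes(phenotype_path, diagnosis_field)
  only_files <- setdiff(ids, pheno$subject_id)
  only_pheno <- setdiff(pheno$subject_id, ids)
  if (length(only_files) || length(only_pheno)) {
    msg <- sprintf(
      "subject reconciliation: %d file(s) without phenotype [%s]; %d phenotype record(s) without files [%s]",
      length(only_files), paste(only_files, collapse = ", "),
      length(only_pheno), paste(only_pheno, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  keep <- ids %in% pheno$subject_id
  subjects <- subjects[keep][order(ids[keep])]
  ids <- sort(ids[keep])
  pheno_m <- pheno[match(ids, pheno$subject_id), , drop = FALSE]
  for (i in seq_along(subjects)) subjects[[i]]$group <- pheno_m$diagnosis[i]
  structure(list(subjects = subjects,
                 phenotype = pheno_m[, c("subject_id", "diagnosis")],
                 config = NULL),
            class = "fnc_cohort",
            unmatched = list(files = only_files, phenotype = only_pheno))
}
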