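LABEL_LEVELS <- c("NONALL", "NONIGE_OR_UNCERTAIN", "IGE")
VTYPE_LEVELS <- c("continuous", "binary", "ordinal", "nominal")
STIMULATIONS <- c("LPS", "PHA")
DURATIONS_H  <- c(24L, 96L)
TIMEPOINTS   <- c("CB", "2m", "6m", "18m")

#' Cytokine panel retained after inter-plate QC
#'
#' The 18 analytes of the multiplex panel that survive the positive-control
#' inter-plate variability filter, in a fixed, sortable order.
#'
#' @return Character vector of 18 cytokine names.
#' @export
cytokine_panel <- function() {
  c("Eotaxin", "FGF", "GCSF", "GMCSF", "IFNgamma", "IL10", "IL12p70",
    "IL15", "IL17", "IL1beta", "IL1ra", "IL2", "IL4", "IL7", "IL9",
    "IP10", "TNFalpha", "VEGF")
}

#' Build the variable metadata table for the standard cohort layout
#'
#' Enumerates the full cytokine condition grid (18 cytokines x
#' \{LPS, PHA\} x \{24h, 96h\} x \{CB, 2m, 6m, 18m\} = 288 continuous
#' variables) followed by the 8 clinical variables. Cytokine variables are
#' named \code{<cytokine>_<stim>_<dur>h_<tp>} (e.g. \code{IL15_PHA_24h_CB});
#' the naming is deterministic and lexicographically sortable, and is used
#' for tie-breaking in rankings.
#'
#' @param cytokines character vector of cytokine names (default the 18-analyte
#'   retained panel).
#' @return A data frame of variable specifications with columns \code{name},
#'   \code{vtype}, \code{provenance}, \code{cytokine}, \code{stimulation},
#'   \code{duration_h}, \code{timepoint}.
#' @export
variable_grid <- function(cytokines = cytokine_panel()) {
  g <- expand.grid(timepoint = TIMEPOINTS, duration_h = DURATIONS_H,
                   stimulation = STIMULATIONS, cytokine = cytokines,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cyt <- data.frame(
    name = sprintf("%s_%s_%dh_%s", g$cytokine, g$stimulation, g$duration_h,
                   g$timepoint),
    vtype = "continuous", provenance = "cytokine",
    cytokine = g$cytokine, stimulation = g$stimulation,
    duration_h = g$duration_h, timepoint = g$timepoint,
    stringsAsFactors = FALSE)
  rbind(cyt, clinical_specs())
}

#' Clinical variable metadata
#'
#' The 8 clinical factors considered alongside the cytokine grid: number of
#' allergic first-degree relatives (ordinal), maternal tobacco exposure
#' during pregnancy, exclusive breastfeeding at the birth, 2-, 6- and
#' 12-month visits, caesarean delivery and presence of pets during pregnancy
#' (all binary).
#'
#' @return Variable-specification data frame (8 rows).
#' @export
clinical_specs <- function() {
  nm <- c("n_allergic_relatives", "tobacco_pregnancy",
          "breastfeeding_birth", "breastfeeding_2m", "breastfeeding_6m",
          "breastfeeding_12m", "caesarean_delivery", "pets_pregnancy")
  data.frame(name = nm,
             vtype = c("ordinal", rep("binary", 7L)),
             provenance = "clinical",
             cytokine = NA_character_, stimulation = NA_character_,
             duration_h = NA_integer_, timepoint = NA_character_,
             stringsAsFactors = FALSE)
}

validate_specs <- function(specs) {
  req <- c("name", "vtype", "provenance", "cytokine", "stimulation",
           "duration_h", "timepoint")
  miss <- setdiff(req, names(specs))
  if (length(miss))
    stop("variable metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(specs$name))
    stop("duplicate variable name(s): ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  bad <- !specs$vtype %in% VTYPE_LEVELS
  if (any(bad))
    stop("unknown vtype for variable(s): ",
         paste(specs$name[bad], collapse = ", "))
  cy <- specs$provenance == "cytokine"
  if (any(cy & (is.na(specs$cytokine) | is.na(specs$stimulation) |
                is.na(specs$duration_h) | is.na(specs$timepoint))))
    stop("cytokine variables must carry all four condition coordinates")
  if (any(cy & specs$vtype != "continuous"))
    stop("cytokine variables must be continuous")
  cl <- specs$provenance == "clinical"
  if (any(cl & (!is.na(specs$cytokine) | !is.na(specs$stimulation) |
                !is.na(specs$duration_h) | !is.na(specs$timepoint))))
    stop("clinical variables must not carry cytokine coordinates")
  invisible(specs)
}

#' Construct and validate a cohort object
#'
#' A cohort bundles the patient-by-variable value matrix (missing cells as
#' \code{NA}), the variable metadata, and the three-class allergy labels
#' (\code{NONALL}, \code{NONIGE_OR_UNCERTAIN}, \code{IGE}).
#'
#' @param values numeric matrix, patients in rows (rownames = patient IDs),
#'   variables in columns (colnames = variable names).
#' @param specs variable-specification data frame as from
#'   \code{\link{variable_grid}}, rows aligned with the matrix columns.
#' @param labels character or factor of per-patient labels.
#' @return An object of class \code{cohort}.
#' @export
cohort <- function(values, specs, labels) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_specs(specs)
  if (ncol(values) != nrow(specs))
    stop("matrix has ", ncol(values), " columns but metadata describes ",
         nrow(specs), " variables")
  if (is.null(colnames(values))) colnames(values) <- specs$name
  if (!identical(colnames(values), specs$name)) {
    if (!setequal(colnames(values), specs$name))
      stop("column names do not match variable metadata: ",
           paste(setdiff(colnames(values), specs$name), collapse = ", "))
    values <- values[, specs$name, drop = FALSE]
  }
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%03d", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate patient ID(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  labels <- as.character(labels)
  if (length(labels) != nrow(values))
    stop("labels length ", length(labels), " != ", nrow(values), " patients")
  bad <- !labels %in% LABEL_LEVELS
  if (any(bad))
    stop("label(s) outside the 3-class vocabulary: ",
         paste(unique(labels[bad]), collapse = ", "))
  for (j in seq_len(ncol(values))) {
    v <- values[, j]; v <- v[!is.na(v)]
    if (specs$vtype[j] == "binary" && length(v) && !all(v %in% c(0, 1)))
      stop("binary variable ", specs$name[j], " has values outside {0,1}")
    if (specs$vtype[j] == "ordinal" && length(v) &&
        (any(v < 0) || any(v != floor(v))))
      stop("ordinal variable ", specs$name[j],
           " has negative or non-integer values")
  }
  structure(list(values = values, specs = specs,
                 labels = factor(labels, levels = LABEL_LEVELS)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$labels)
  cat("Cohort: ", nrow(x$values), " patients x ", ncol(x$values),
      " variables (", sum(x$specs$provenance == "cytokine"), " cytokine, ",
      sum(x$specs$provenance == "clinical"), " clinical)\n", sep = "")
  cat("Labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("Missing cells: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
summary.cohort <- function(object, ...) cohort_summary(object)

#' Define a binary classification task over the three-class labels
#'
#' @param task_id identifier, e.g. \code{"ALLERGY"} or \code{"IGE"}.
#' @param positive_classes,negative_classes disjoint, non-empty subsets of
#'   the label vocabulary.
#' @return An object of class \code{label_task}.
#' @export
label_task <- function(task_id, positive_classes, negative_classes) {
  stopifnot(is.character(task_id), length(task_id) == 1L)
  if (!length(positive_classes) || !length(negative_classes))
    stop("positive and negative class sets must be non-empty")
  if (length(intersect(positive_classes, negative_classes)))
    stop("positive and negative class sets overlap")
  bad <- setdiff(c(positive_classes, negative_classes), LABEL_LEVELS)
  if (length(bad)) stop("unknown label class: ", paste(bad, collapse = ", "))
  structure(list(task_id = task_id, positive_classes = positive_classes,
                 negative_classes = negative_classes), class = "label_task")
}

#' Standard allergy prediction task
#'
#' Positives are allergic children; by default the pooled non-IgE-mediated /
#' uncertain group counts as allergic (mirroring the 30-patient pooled group
#' of the cytokine sub-cohort). Set \code{include_uncertain = FALSE} to
#' restrict positives to IgE-mediated children only.
#'
#' @param include_uncertain logical.
#' @return A \code{label_task}.
#' @export
allergy_task <- function(include_uncertain = TRUE) {
  pos <- if (include_uncertain) c("IGE", "NONIGE_OR_UNCERTAIN") else "IGE"
  label_task("ALLERGY", pos, "NONALL")
}

#' IgE-mediated allergy prediction task
#'
#' IgE-mediated allergic children against the rest of the cohort.
#'
#' @return A \code{label_task}.
#' @export
ige_task <- function()
  label_task("IGE", "IGE", c("NONALL", "NONIGE_OR_UNCERTAIN"))

#' Binarize cohort labels for a task
#'
#' Patients whose class belongs to neither side of the task are dropped
#' (their count is reported via \code{message} and the \code{"dropped"}
#' attribute).
#'
#' @param x a \code{cohort}.
#' @param task a \code{label_task}.
#' @return Integer vector of 1 (positive) / 0 (negative), named by patient
#'   ID, aligned with the retained patients; attributes \code{keep} (row
#'   indices retained) and \code{dropped} (count removed).
#' @export
binarize <- function(x, task) {
  stopifnot(inherits(x, "cohort"), inherits(task, "label_task"))
  lab <- as.character(x$labels)
  keep <- which(lab %in% c(task$positive_classes, task$negative_classes))
  dropped <- length(lab) - length(keep)
  if (dropped > 0L)
    message(dropped, " patient(s) outside task ", task$task_id, " dropped")
  y <- as.integer(lab[keep] %in% task$positive_classes)
  if (!any(y == 1L) || !any(y == 0L))
    stop("degenerate task ", task$task_id,
         ": zero positives or zero negatives")
  names(y) <- rownames(x$values)[keep]
  attr(y, "keep") <- keep
  attr(y, "dropped") <- dropped
  y
}

#' Subset a cohort by patients and/or variables
#'
#' @param x a \code{cohort}.
#' @param patients row indices (or logical/character) to keep.
#' @param variables column indices (or logical/character) to keep.
#' @return A \code{cohort}.
#' @export
subset_cohort <- function(x, patients = NULL, variables = NULL) {
  stopifnot(inherits(x, "cohort"))
  v <- x$values; s <- x$specs; l <- as.character(x$labels)
  if (!is.null(patients)) {
    v <- v[patients, , drop = FALSE]
    l <- l[if (is.character(patients)) match(patients, rownames(x$values))
           else patients]
  }
  if (!is.null(variables)) {
    v <- v[, variables, drop = FALSE]
    s <- s[match(colnames(v), s$name), , drop = FALSE]
    rownames(s) <- NULL
  }
  cohort(v, s, l)
}

#' Read a cohort from CSV with a YAML metadata sidecar
#'
#' The CSV holds one row per patient with a \code{patient_id} column, a
#' \code{label} column and one column per variable; empty cells mark missing
#' values. The sidecar is a YAML list of variable specifications
#' (name/vtype/provenance and, for cytokine variables, the condition
#' coordinates).
#'
#' @param path CSV file path.
#' @param schema YAML sidecar path (default \code{<path>} with a
#'   \code{.yaml} extension appended after stripping \code{.csv}).
#' @return A validated \code{cohort}.
#' @export
read_cohort <- function(path, schema = default_schema_path(path)) {
  specs <- schema_from_yaml(schema)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character", na.strings = "")
  for (col in c("patient_id", "label"))
    if (!col %in% names(df)) stop("cohort CSV lacks column: ", col)
  varcols <- setdiff(names(df), c("patient_id", "label"))
  miss <- setdiff(specs$name, varcols)
  if (length(miss))
    stop("metadata/column mismatch; missing from CSV: ",
         paste(miss, collapse = ", "))
  extra <- setdiff(varcols, specs$name)
  if (length(extra))
    stop("metadata/column mismatch; undeclared column(s): ",
         paste(extra, collapse = ", "))
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ID(s): ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  m <- vapply(specs$name, function(v) as.numeric(df[[v]]),
              numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df),
              dimnames = list(df$patient_id, specs$name))
  cohort(m, specs, df$label)
}

default_schema_path <- function(path)
  paste0(sub("\\.csv$", "", path), ".vars.yaml")

schema_from_yaml <- function(schema) {
  y <- yaml::read_yaml(schema)
  if (!is.null(y$variables)) y <- y$variables
  specs <- do.call(rbind, lapply(y, function(v) {
    data.frame(name = v$name, vtype = v$vtype, provenance = v$provenance,
               cytokine = v$cytokine %||% NA_character_,
               stimulation = v$stimulation %||% NA_character_,
               duration_h = as.integer(v$duration_h %||% NA_integer_),
               timepoint = v$timepoint %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  validate_specs(specs)
}

#' Write a cohort to CSV plus YAML metadata sidecar
#'
#' Missing values become empty cells; \code{read_cohort} restores the cohort
#' value-identically, including the missingness pattern.
#'
#' @param x a \code{cohort}.
#' @param path output CSV path.
#' @param schema output YAML path.
#' @return Invisibly, \code{path}.
#' @export
write_cohort <- function(x, path, schema = default_schema_path(path)) {
  stopifnot(inherits(x, "cohort"))
  df <- data.frame(patient_id = rownames(x$values),
                   label = as.character(x$labels),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  vars <- lapply(seq_len(nrow(x$specs)), function(i) {
    s <- as.list(x$specs[i, ])
    s[!vapply(s, function(z) is.na(z), logical(1))]
  })
  yaml::write_yaml(list(variables = vars), schema)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
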