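#' Build a paired treatment/control sample design
#'
#' Emulates the pooled-competition plate design: each treatment replicate is
#' grown alongside an in-plate control it is paired with for the downstream
#' paired fitness test; designated compounds (in the study, MMS and QUADRIS)
#' are unpaired and are contrasted against a shared pool of unpaired control
#' samples instead.
#'
#' @param compounds character vector of inhibitor names.
#' @param n_replicates biological replicates per compound (>= 2, default 3).
#' @param unpaired character vector of compounds analysed unpaired.
#' @return data frame of class `design_table` with columns `sample_id`,
#'   `compound`, `role` ("treatment"/"control"), `pair_id` (NA when unpaired),
#'   `batch`, `replicate`.
#' @export
build_design <- function(compounds, n_replicates = 3, unpaired = character()) {
  stopifnot(length(compounds) >= 1, n_replicates >= 2)
  if (anyDuplicated(compounds)) stop("duplicate compound names")
  if (!all(unpaired %in% compounds)) stop("unpaired compounds not in 'compounds'")
  rows <- list()
  for (cmp in compounds) {
    for (r in seq_len(n_replicates)) {
      batch <- sprintf("batch%d", r)
      if (cmp %in% unpaired) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_T%d", cmp, r), compound = cmp,
          role = "treatment", pair_id = NA_character_, batch = batch,
          replicate = r, stringsAsFactors = FALSE)
      } else {
        pid <- sprintf("%s_p%d", cmp, r)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_T%d", cmp, r), compound = cmp,
          role = "treatment", pair_id = pid, batch = batch,
          replicate = r, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sprintf("%s_C%d", cmp, r), compound = "control",
          role = "control", pair_id = pid, batch = batch,
          replicate = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(unpaired)) {
    for (r in seq_len(n_replicates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("unpairedC%d", r), compound = "control",
        role = "control", pair_id = NA_character_,
        batch = sprintf("batch%d", r), replicate = r, stringsAsFactors = FALSE)
    }
  }
  des <- do.call(rbind, rows)
  rownames(des) <- NULL
  class(des) <- c("design_table", "data.frame")
  validate_design(des)
}

#' Validate a sample design table
#'
#' @param design data frame per [build_design()].
#' @return the design, invisibly, classed `design_table`.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "compound", "role", "pair_id", "batch", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!all(design$role %in% c("treatment", "control"))) {
    stop("role must be 'treatment' or 'control'")
  }
  tr <- design[design$role == "treatment" & !is.na(design$pair_id), , drop = FALSE]
  ctl_pairs <- design$pair_id[design$role == "control"]
  bad <- setdiff(tr$pair_id, ctl_pairs)
  if (length(bad)) {
    stop("treatment pair_id without matching control sample: ",
         paste(bad, collapse = ", "))
  }
  cmp <- design$compound[design$role == "treatment"]
  reps <- table(cmp)
  if (any(reps < 2)) {
    stop("compounds need >= 2 treatment replicates: ",
         paste(names(reps)[reps < 2], collapse = ", "))
  }
  if (!inherits(design, "design_table")) {
    class(design) <- c("design_table", class(design))
  }
  invisible(design)
}

#' Compounds present as treatments in a design
#' @param design a `design_table`.
#' @return character vector of compound names.
#' @export
design_compounds <- function(design) {
  unique(design$compound[design$role == "treatment"])
}

#' Write / read a design table as TSV
#' @param design a `design_table`.
#' @param file path.
#' @export
write_design <- function(design, file) write_tsv(design, file)

#' @rdname write_design
#' @export
read_design <- function(file) {
  d <- read_tsv(file)
  d$pair_id <- as.character(d$pair_id)
  d$pair_id[d$pair_id %in% c("NA", "")] <- NA_character_
  validate_design(d)
  class(d) <- c("design_table", "data.frame")
  d
}
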