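#' Construct an atlas table
#'
#' An atlas assigns each ROI a name and a resting-state-network label
#' (the seven canonical cortical networks plus a "subcortical" label for
#' subcortical and cerebellar regions).
#'
#' @param roi_names Character vector of unique ROI names.
#' @param networks Character vector of network labels, one per ROI.
#' @return A `data.frame` with columns `roi_index` (0-based), `roi_name`,
#'   `network`, of class `fc_atlas`.
#' @export
fc_atlas <- function(roi_names, networks) {
  R <- length(roi_names)
  if (R < 2) stop("invalid atlas: need at least 2 ROIs", call. = FALSE)
  if (anyDuplicated(roi_names)) stop("ROI names must be unique", call. = FALSE)
  if (length(networks) != R || anyNA(networks) || any(!nzchar(networks)))
    stop("every ROI needs a network label", call. = FALSE)
  out <- data.frame(roi_index = 0:(R - 1), roi_name = as.character(roi_names),
                    network = as.character(networks), stringsAsFactors = FALSE)
  class(out) <- c("fc_atlas", "data.frame")
  out
}

#' Default desk-scale atlas
#'
#' A 50-ROI stand-in atlas with the eight network labels distributed over
#' the ROIs; used by the synthetic-data defaults.
#'
#' @param R Number of ROIs.
#' @return An [fc_atlas()] table.
#' @export
default_atlas <- function(R = 50) {
  nets <- c("visual", "somatomotor", "DAN", "VAN", "limbic", "FPN", "DMN",
            "subcortical")
  fc_atlas(sprintf("ROI%03d", 0:(R - 1)), rep_len(nets, R))
}

validate_participants <- function(participants) {
  need <- c("subject_id", "site", "diagnosis", "age", "sex")
  miss <- setdiff(need, names(participants))
  if (length(miss))
    stop("participant table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(participants$subject_id))
    stop("subject_id must be unique", call. = FALSE)
  if (!all(participants$diagnosis %in% c(0, 1)))
    stop("diagnosis must be coded 0 (control) / 1 (patient)", call. = FALSE)
  ok_age <- is.na(participants$age) | participants$age > 0
  if (!all(ok_age)) stop("ages must be positive", call. = FALSE)
  invisible(participants)
}

#' Bundle participants, connectivity matrix and atlas into a dataset
#'
#' The central container of the package: a participant table (subject id,
#' site, diagnosis coded 0 = control / 1 = patient, age in years, sex)
#' aligned row-by-row with a subjects x edges matrix of Fisher
#' z-transformed connectivity values.
#'
#' @param participants `data.frame` with columns `subject_id`, `site`,
#'   `diagnosis`, `age`, `sex`.
#' @param fc Numeric matrix, subjects x edges, all values finite; row `k`
#'   belongs to participant `k`.
#' @param atlas An [fc_atlas()]; `ncol(fc)` must equal
#'   `edge_count(nrow(atlas))`.
#' @param name Dataset name used in reports.
#' @return An object of class `fc_dataset` (a list with elements
#'   `participants`, `fc`, `atlas`, `name`).
#' @export
fc_dataset <- function(participants, fc, atlas, name = "dataset") {
  validate_participants(participants)
  fc <- as.matrix(fc)
  if (nrow(fc) != nrow(participants))
    stop("alignment error: fc has ", nrow(fc), " rows but participant table has ",
         nrow(participants), call. = FALSE)
  R <- nrow(atlas)
  if (ncol(fc) != edge_count(R))
    stop("fc has ", ncol(fc), " columns; atlas with ", R, " ROIs implies ",
         edge_count(R), call. = FALSE)
  bad <- which(!is.finite(fc), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite fc value for subject '",
         participants$subject_id[bad[1, 1]], "' at edge ", bad[1, 2] - 1L,
         call. = FALSE)
  rownames(fc) <- participants$subject_id
  colnames(fc) <- edge_labels(R)
  structure(list(participants = participants, fc = fc, atlas = atlas,
                 name = name),
            class = "fc_dataset")
}

#' @export
print.fc_dataset <- function(x, ...) {
  p <- x$participants
  cat(sprintf("<fc_dataset '%s'> %d subjects (%d controls / %d patients), %d sites, %d edges (R = %d)\n",
              x$name, nrow(p), sum(p$diagnosis == 0), sum(p$diagnosis == 1),
              length(unique(p$site)), ncol(x$fc), nrow(x$atlas)))
  invisible(x)
}

#' Number of subjects / edges in a dataset
#' @param dataset An `fc_dataset`.
#' @return Integer.
#' @export
n_subjects <- function(dataset) nrow(dataset$fc)

#' @rdname n_subjects
#' @export
n_edges <- function(dataset) ncol(dataset$fc)

#' Subset a dataset by subject
#' @param dataset An `fc_dataset`.
#' @param idx Row indices or logical mask.
#' @return An `fc_dataset` with the selected subjects.
#' @export
subset_subjects <- function(dataset, idx) {
  fc_dataset(dataset$participants[idx, , drop = FALSE],
             dataset$fc[idx, , drop = FALSE],
             dataset$atlas, dataset$name)
}

#' Split a dataset into developmental stages
#'
#' Stages follow the strict age bounds used for the developmental analyses:
#' children are `age < 12`, adolescents `12 < age < 18`, adults `age >= 18`.
#' Subjects aged exactly 12 fall in neither the child nor the adolescent
#' stage (the bounds are strict); subjects with missing age are dropped with
#' a warning.
#'
#' @param dataset An `fc_dataset`.
#' @return Named list of `fc_dataset`s: `child`, `adolescent`, `adult`
#'   (possibly with zero subjects).
#' @export
split_by_stage <- function(dataset) {
  age <- dataset$participants$age
  if (anyNA(age)) {
    warning("excluding ", sum(is.na(age)), " subject(s) with missing age: ",
            paste(dataset$participants$subject_id[is.na(age)], collapse = ", "))
  }
  pick <- function(mask, stage) {
    mask[is.na(mask)] <- FALSE
    out <- subset_subjects(dataset, mask)
    out$name <- paste0(dataset$name, ".", stage)
    out
  }
  list(child      = pick(age < 12, "child"),
       adolescent = pick(age > 12 & age < 18, "adolescent"),
       adult      = pick(age >= 18, "adult"))
}

fmt_full <- function(x) sprintf("%.17g", x)

#' Read / write a dataset as delimited text
#'
#' `write_fc_dataset()` writes three tab-separated files into `dir`:
#' `participants.tsv` (`subject_id site diagnosis age sex`), `fc.tsv`
#' (subjects x edges with `e<i>_<j>` headers and a leading `subject_id`
#' column, values printed with 17 significant digits so the round trip is
#' bit-stable), and `atlas.tsv` (`roi_index roi_name network`).
#' `read_fc_dataset()` reads them back, verifying subject alignment by id.
#'
#' @param dataset An `fc_dataset`.
#' @param dir Output directory (created if needed).
#' @param participants_path,fc_path,atlas_path File paths.
#' @param name Dataset name to attach on read.
#' @return `write_fc_dataset()`: named character vector of the paths
#'   written. `read_fc_dataset()`: an `fc_dataset`.
#' @export
write_fc_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(participants = file.path(dir, "participants.tsv"),
             fc = file.path(dir, "fc.tsv"),
             atlas = file.path(dir, "atlas.tsv"))
  p <- dataset$participants
  p$age <- fmt_full(p$age)
  utils::write.table(p, paths["participants"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fc_chr <- apply(dataset$fc, 2, fmt_full)
  if (is.null(dim(fc_chr))) fc_chr <- matrix(fc_chr, nrow = nrow(dataset$fc))
  out <- data.frame(subject_id = dataset$participants$subject_id, fc_chr,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("subject_id", colnames(dataset$fc))
  utils::write.table(out, paths["fc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(dataset$atlas), paths["atlas"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths
}

#' @rdname write_fc_dataset
#' @export
read_fc_dataset <- function(participants_path, fc_path, atlas_path,
                            name = "dataset") {
  participants <- utils::read.table(participants_path, header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE,
                                    colClasses = c(subject_id = "character"))
  atl <- utils::read.table(atlas_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  atlas <- fc_atlas(atl$roi_name, atl$network)
  fc_tab <- utils::read.table(fc_path, header = TRUE, sep = "\t",
                              check.names = FALSE,
                              colClasses = c(subject_id = "character"))
  if (!identical(fc_tab$subject_id, participants$subject_id))
    stop("alignment error: subject ids in fc matrix do not match participant table",
         call. = FALSE)
  fc <- as.matrix(fc_tab[, -1, drop = FALSE])
  fc_dataset(participants, fc, atlas, name)
}
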