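#' Write and read subject tables
#'
#' Plain CSV/TSV round-trip for cohort tables (delimiter chosen from the
#' file extension).
#'
#' @param subjects Cohort tibble.
#' @param path Output path (`.csv` or `.tsv`).
#' @export
write_subject_table <- function(subjects, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(subjects), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, sep = sep, header = TRUE,
                                      stringsAsFactors = FALSE))
}

#' Write a contrast matrix as NIfTI
#'
#' Stores the subjects x voxels matrix as a 4-D NIfTI volume (voxels laid
#' out along the first axis, one volume per subject) together with a mask
#' volume and a JSON sidecar holding the subject order and contrast name.
#'
#' @param maps A [contrast_matrix()].
#' @param path Output `.nii` / `.nii.gz` path (a `.json` sidecar and a
#'   `_mask` volume are written next to it).
#' @export
write_contrast_nifti <- function(maps, path) {
  V <- maps$values
  arr <- array(t(V), dim = c(ncol(V), 1, 1, nrow(V)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  RNifti::writeNifti(RNifti::asNifti(array(1L, dim = c(ncol(V), 1, 1))), mask_path)
  jsonlite::write_json(list(subjects = maps$subjects, contrast = maps$contrast,
                            demand = maps$demand, n_voxels = ncol(V)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contrast_nifti
#' @export
read_contrast_nifti <- function(path) {
  arr <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  V <- t(matrix(arr, nrow = dim(arr)[1]))
  rownames(V) <- meta$subjects
  contrast_matrix(V, contrast = meta$contrast,
                  demand = meta$demand %||% NA_real_)
}

#' Write a consensus (or any voxel) map as NIfTI
#'
#' @param map Numeric voxel vector.
#' @param path Output `.nii` / `.nii.gz` path.
#' @export
write_voxel_map_nifti <- function(map, path) {
  RNifti::writeNifti(RNifti::asNifti(array(map, dim = c(length(map), 1, 1))), path)
  invisible(path)
}

#' Matrix container: TSV values + JSON sidecar
#'
#' Text-based container for subjects x features matrices: `<prefix>.tsv`
#' holds the values, `<prefix>.json` the subject order and feature count.
#'
#' @param mat Numeric matrix with subject rownames.
#' @param prefix Path prefix (without extension).
#' @export
write_matrix_container <- function(mat, prefix) {
  utils::write.table(mat, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(subjects = rownames(mat), n_features = ncol(mat)),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_matrix_container
#' @export
read_matrix_container <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  mat <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), sep = "\t"))
  dimnames(mat) <- list(meta$subjects, NULL)
  mat
}

#' Write and read a parcellation as CSV
#'
#' @param parcellation A [generate_parcellation()] object.
#' @param path Output `.csv` path.
#' @export
write_parcellation <- function(parcellation, path) {
  df <- data.frame(voxel = seq_along(parcellation$labels),
                   label = parcellation$labels,
                   network = names(parcellation$networks)[parcellation$labels])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nets <- unique(df[order(df$label), c("label", "network")])
  structure(list(labels = df$label[order(df$voxel)],
                 networks = setNames(nets$label, nets$network)),
            class = "parcellation")
}

#' Serialize a fitted GCA factor model to JSON
#'
#' Stores loadings, uniquenesses, scoring weights and train standardization
#' statistics so held-out subjects can be scored later.
#'
#' @param model A [fit_bifactor()] model.
#' @param path Output `.json` path.
#' @export
write_gca_model <- function(model, path) {
  jsonlite::write_json(
    list(tests = model$tests, lambda_g = model$lambda_g,
         lambda_f = as.data.frame(model$lambda_f), psi = model$psi,
         weights = model$weights, train_means = model$train_means,
         train_sds = model$train_sds, omega_h = model$omega_h,
         srmr = model$srmr, n = model$n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gca_model
#' @export
read_gca_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lf <- as.matrix(j$lambda_f)
  rownames(lf) <- j$tests
  structure(list(tests = j$tests,
                 lambda_g = setNames(j$lambda_g, j$tests),
                 lambda_f = lf,
                 psi = setNames(j$psi, j$tests),
                 weights = setNames(j$weights, j$tests),
                 train_means = setNames(j$train_means, j$tests),
                 train_sds = setNames(j$train_sds, j$tests),
                 omega_h = j$omega_h, srmr = j$srmr,
                 first_order = NULL, heywood = NA, n = j$n),
            class = "gca_factor_model")
}

#' Serialize a fitted BBS model with its basis
#'
#' Writes the basis components and train voxel means as TSV alongside a JSON
#' file holding the coefficients and metadata, so predictions can be made in
#' a later session without refitting.
#'
#' @param basis A [build_basis()] object.
#' @param model The [fit_bbs()] model fitted on that basis.
#' @param prefix Path prefix; writes `<prefix>_components.tsv` and
#'   `<prefix>.json`.
#' @export
write_bbs_model <- function(basis, model, prefix) {
  utils::write.table(basis$components, paste0(prefix, "_components.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(beta = model$beta, gamma = model$gamma, K = basis$K,
         p = model$p, center = basis$center, eigenvalues = basis$eigenvalues,
         n_train = basis$n_train),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_bbs_model
#' @export
read_bbs_model <- function(prefix) {
  j <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  comp <- as.matrix(utils::read.table(paste0(prefix, "_components.tsv"),
                                      sep = "\t"))
  dimnames(comp) <- NULL
  basis <- structure(list(components = comp, eigenvalues = j$eigenvalues,
                          center = j$center, K = j$K, n_train = j$n_train),
                     class = "basis_set")
  model <- structure(list(beta = j$beta, gamma = j$gamma, K = j$K, p = j$p),
                     class = "bbs_model")
  list(basis = basis, model = model)
}
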