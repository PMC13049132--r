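#' Persist a structure set as a plain-text container
#'
#' Writes one directory holding a YAML header (grid dims, spacing, origin,
#' structure names, optional phantom configuration) and one CSV of linear
#' voxel indices per structure mask. Plain text keeps the container portable
#' and diff-able.
#'
#' @param structures a [structure_set()].
#' @param path directory to create/write.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(structures, path) {
  stopifnot(inherits(structures, "structure_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  g <- structures$grid
  hdr <- list(dims = as.integer(g$dims), spacing = g$spacing, origin = g$origin,
              structures = names(structures$masks))
  if (!is.null(structures$config)) hdr$config <- structures$config
  yaml::write_yaml(hdr, file.path(path, "grid.yaml"))
  for (nm in names(structures$masks))
    utils::write.csv(data.frame(index = which(as.vector(structures$masks[[nm]]))),
                     file.path(path, paste0(nm, ".csv")), row.names = FALSE)
  invisible(path)
}

#' @rdname write_phantom
#' @param path directory written by [write_phantom()].
#' @return A [structure_set()]; the ventricular distance field is recomputed.
#' @export
read_phantom <- function(path) {
  hdr <- yaml::read_yaml(file.path(path, "grid.yaml"))
  grid <- voxel_grid(hdr$dims, unlist(hdr$spacing), unlist(hdr$origin))
  masks <- lapply(hdr$structures, function(nm) {
    idx <- utils::read.csv(file.path(path, paste0(nm, ".csv")))$index
    m <- array(FALSE, dim = grid$dims)
    m[idx] <- TRUE
    m
  })
  names(masks) <- hdr$structures
  ss <- structure_set(grid, masks)
  if ("Ventricles" %in% names(masks) && any(masks$Ventricles))
    ss$vs_distance <- distance_field(grid, masks$Ventricles)
  if (!is.null(hdr$config)) ss$config <- hdr$config
  ss
}

#' Persist influence matrices as Matrix Market files
#'
#' Writes `D.mtx`, `L.mtx`, `M.mtx` plus a YAML sidecar with the grid, model
#' coefficients, cutoff and beam specifications; `C` is reassembled on read
#' from `beta1 * D + beta2 * M`.
#'
#' @param influence a [build_influence()] result.
#' @param path directory to create/write.
#' @return `path`, invisibly.
#' @export
write_influence <- function(influence, path) {
  stopifnot(inherits(influence, "influence_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(influence$D, file.path(path, "D.mtx"))
  Matrix::writeMM(influence$L, file.path(path, "L.mtx"))
  Matrix::writeMM(influence$M, file.path(path, "M.mtx"))
  g <- influence$grid
  yaml::write_yaml(
    list(dims = as.integer(g$dims), spacing = g$spacing, origin = g$origin,
         beta1 = influence$beta1, beta2 = influence$beta2,
         cutoff = influence$cutoff, m = influence$m,
         beams = lapply(influence$beams, unclass)),
    file.path(path, "influence.yaml"))
  utils::write.csv(influence$spots, file.path(path, "spots.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_influence
#' @param path directory written by [write_influence()].
#' @export
read_influence <- function(path) {
  hdr <- yaml::read_yaml(file.path(path, "influence.yaml"))
  D <- methods::as(Matrix::readMM(file.path(path, "D.mtx")), "CsparseMatrix")
  L <- methods::as(Matrix::readMM(file.path(path, "L.mtx")), "CsparseMatrix")
  M <- methods::as(Matrix::readMM(file.path(path, "M.mtx")), "CsparseMatrix")
  grid <- voxel_grid(hdr$dims, unlist(hdr$spacing), unlist(hdr$origin))
  beams <- lapply(hdr$beams, function(b) do.call(beam_spec, b))
  structure(list(D = D, L = L, M = M,
                 C = hdr$beta1 * D + hdr$beta2 * M, m = hdr$m,
                 spots = utils::read.csv(file.path(path, "spots.csv")),
                 beta1 = hdr$beta1, beta2 = hdr$beta2, cutoff = hdr$cutoff,
                 grid = grid, beams = beams),
            class = "influence_set")
}

#' Read/write POLO model parameters as YAML
#'
#' @param params a [polo_params()].
#' @param path YAML file path.
#' @return `path` / a [polo_params()].
#' @export
write_polo_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_polo_params
#' @export
read_polo_params <- function(path) do.call(polo_params, yaml::read_yaml(path))

#' Export an iteration trace or report tables to CSV
#'
#' @param result a `plan_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
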