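#' Write a volume to NIfTI-1
#'
#' Writes values on a [voxel_grid()] as float32 NIfTI-1, with the voxel
#' sizes in the pixdim fields and the grid origin in an axis-aligned
#' sform/qform, so that a write-then-read round-trip reproduces both the
#' float32 values bit-exactly and the grid.
#'
#' @param volume A [mumap()], a [hardware_profile()], or a list with
#'   elements `values` (3-D array) and `grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "hardware_profile"))
    volume <- list(values = array(as.numeric(volume$mask), volume$grid$dims),
                   grid = volume$grid)
  grid <- volume$grid
  vals <- array(as.numeric(volume$values), grid$dims)
  attr(vals, "pixdim") <- grid$voxel_size
  img <- RNifti::asNifti(vals, datatype = "float")
  # axis-aligned affine: voxel (0,0,0) centre at origin + voxel_size/2
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid$voxel_size)
  aff[1:3, 4] <- grid$origin + grid$voxel_size / 2
  RNifti::qform(img) <- structure(aff, code = 1L)
  RNifti::sform(img) <- structure(aff, code = 1L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param grid Optional expected [voxel_grid()]; dimensions and voxel sizes
#'   are validated against it and mismatches raise an error naming the axes.
#' @param mask Assert the volume is binary and return a
#'   [hardware_profile()].
#' @return A list with `values` and `grid` (or a `hardware_profile` when
#'   `mask = TRUE`).
#' @export
read_volume <- function(path, grid = NULL, mask = FALSE) {
  if (!file.exists(path)) stop(sprintf("volume file '%s' not found", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  origin <- aff[1:3, 4] - vs / 2
  g <- voxel_grid(dim(img), vs, origin)
  if (!is.null(grid)) {
    bad_dim <- which(g$dims != grid$dims)
    if (length(bad_dim))
      stop(sprintf("volume dimensions differ from the expected grid on axis %s (%s vs %s)",
                   paste(c("x", "y", "z")[bad_dim], collapse = ", "),
                   paste(g$dims[bad_dim], collapse = ", "),
                   paste(grid$dims[bad_dim], collapse = ", ")), call. = FALSE)
    bad_vs <- which(abs(g$voxel_size - grid$voxel_size) > 1e-4)
    if (length(bad_vs))
      stop(sprintf("voxel size differs from the expected grid on axis %s",
                   paste(c("x", "y", "z")[bad_vs], collapse = ", ")),
           call. = FALSE)
  }
  if (mask) {
    if (!all(abs(vals) < 1e-6 | abs(vals - 1) < 1e-6))
      stop(sprintf("volume '%s' is not a binary mask", path), call. = FALSE)
    return(hardware_profile(vals > 0.5, g, provenance = path))
  }
  list(values = vals, grid = g)
}

#' Write / read a sinogram as a columnar text table
#'
#' CSV with a commented header carrying the acquisition metadata (flavor,
#' duration, noise mode, seed) and one row per LOR with detector indices,
#' endpoint coordinates, expected counts and realized counts.
#'
#' @param sinogram A `sinogram`.
#' @param path Output path.
#' @return `path` invisibly ([write_sinogram()]); a `sinogram`
#'   ([read_sinogram()]).
#' @export
write_sinogram <- function(sinogram, path) {
  stopifnot(inherits(sinogram, "sinogram"))
  lors <- attr(sinogram, "lors")
  tab <- cbind(lors[c("lor_id", "t1", "a1", "t2", "a2",
                      "x1", "y1", "z1", "x2", "y2", "z2", "multiplicity")],
               expected = sinogram$expected, counts = sinogram$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# flavor: %s", attr(sinogram, "flavor")),
               sprintf("# duration_s: %.10g", attr(sinogram, "duration")),
               sprintf("# noise: %s", attr(sinogram, "noise")),
               sprintf("# seed: %d", attr(sinogram, "seed"))), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) stop(sprintf("sinogram file '%s' not found", path),
                               call. = FALSE)
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  tab <- utils::read.csv(path, comment.char = "#")
  lors <- tab[c("lor_id", "t1", "a1", "t2", "a2",
                "x1", "y1", "z1", "x2", "y2", "z2", "multiplicity")]
  class(lors) <- c("lor_set", "data.frame")
  acq <- acquisition_config(duration = as.numeric(meta$duration_s),
                            noise = meta$noise, seed = as.integer(meta$seed))
  new_sinogram(lors, tab$expected, tab$counts, meta$flavor, acq)
}

#' Write / read a run configuration
#'
#' YAML with a `schema_version` field. [read_run_config()] validates the
#' schema version and that any referenced files exist.
#'
#' @param config A run-configuration list (see [run_pipeline()]).
#' @param path YAML path.
#' @return `path` invisibly; [read_run_config()] returns the list.
#' @export
write_run_config <- function(config, path) {
  config$schema_version <- config$schema_version %||% 1L
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  config <- yaml::read_yaml(path)
  if (is.null(config$schema_version))
    stop("config has no 'schema_version' field", call. = FALSE)
  if (config$schema_version != 1L)
    stop(sprintf("unsupported config schema version %s", config$schema_version),
         call. = FALSE)
  for (f in c(config$phantom$path, config$compare$ct_volume))
    if (!is.null(f) && !file.exists(f))
      stop(sprintf("referenced file '%s' does not exist", f), call. = FALSE)
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full transmission-based AC pipeline
#'
#' Chains the modules into the hardware mu-map workflow: build the scanner
#' geometry, grid and hardware profile; enumerate the LORs subtended by the
#' line source; simulate (or later, load) the blank scan; trace every LOR
#' through the grid; forward-model the transmission scan through the true
#' attenuation map; estimate the hardware LAC by Beer-Lambert inversion;
#' assemble the mu-map; and optionally compare against a CT-derived
#' (bilinear) map. All artifacts are written with a provenance sidecar
#' (package version, seed, configuration hash, filtered-LOR counts). Given
#' the same configuration and seed the outputs are byte-identical.
#'
#' @param config Configuration list (or path to a YAML written by
#'   [write_run_config()]): fields `geometry`, `grid`, `source`,
#'   `acquisition`, `phantom` (`type` `"cylinder_shell"`, `"slab"` or
#'   `"volume"`; `mu` true LAC for simulation), `lor_sampling`, `filters`,
#'   `seed`, `output_dir`, optional `compare$ct_volume`.
#' @param seed Overrides `config$seed`.
#' @return A list with the `estimate`, the `mumap`, per-stage objects and
#'   the written `paths`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  geom <- stage("geometry", do.call(scanner_geometry, config$geometry %||% list()))
  grid <- stage("grid", do.call(voxel_grid, config$grid %||% list()))
  src <- stage("source", do.call(line_source, config$source %||% list()))
  acq <- stage("acquisition", do.call(acquisition_config,
                                      utils::modifyList(config$acquisition %||% list(),
                                                        list(seed = seed))))
  profile <- stage("phantom", {
    ph <- config$phantom
    switch(ph$type %||% "cylinder_shell",
           cylinder_shell = do.call(make_cylinder_shell,
                                    c(list(grid = grid), ph$args %||% list())),
           slab = do.call(make_slab, c(list(grid = grid), ph$args %||% list())),
           volume = read_volume(ph$path, grid = grid, mask = TRUE),
           stop(sprintf("unknown phantom type '%s'", ph$type)))
  })
  true_mu <- config$phantom$mu %||% 0.10698

  lors <- stage("enumerate_lors", do.call(enumerate_source_lors,
    c(list(geom = geom, src = src, seed = seed), config$lor_sampling %||% list())))
  blank <- stage("simulate_blank",
                 simulate_blank(geom, src, acq, lors = lors,
                                weight_mode = config$weight_mode %||% "pair"))
  segments <- stage("trace", trace_lors(lors, grid,
                                        mode = config$trace_mode %||% "3d"))
  truth <- stage("true_mumap", assemble_mumap(true_mu, profile))
  tx <- stage("simulate_transmission",
              simulate_transmission(blank, segments, truth))
  lens <- stage("masked_lengths", masked_lengths(segments, profile))
  est <- stage("estimate", do.call(estimate_lac,
    c(list(blank = blank, tx = tx, lengths_mm = lens),
      config$filters %||% list())))
  map <- stage("assemble", assemble_mumap(est, profile))

  paths <- list()
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$output_dir, f)
    paths$mumap <- write_volume(map, out("mumap_tx.nii.gz"))
    paths$blank <- write_sinogram(blank, out("blank.csv"))
    paths$tx <- write_sinogram(tx, out("transmission.csv"))
    prov <- list(
      package = "txac",
      package_version = as.character(utils::packageVersion("txac")),
      seed = seed,
      config_hash = config_hash(config),
      lac_estimate = est$mu, lac_sd = est$sd,
      n_lors_used = est$n_used, n_lors_supplied = est$n_supplied,
      n_zero_tx = est$diagnostics$n_zero_tx,
      n_short_chord = est$diagnostics$n_short_chord)
    yaml::write_yaml(prov, out("provenance.yaml"))
    paths$provenance <- out("provenance.yaml")
  }

  result <- list(estimate = est, mumap = map, profile = profile,
                 blank = blank, tx = tx, lors = lors, paths = paths)

  if (!is.null(config$compare$ct_volume)) {
    ct <- stage("ctac", {
      hu <- read_volume(config$compare$ct_volume, grid = grid)
      hu_to_lac(hu, do.call(bilinear_params, config$compare$bilinear %||% list()))
    })
    result$ct_mumap <- ct
    result$rpd_vs_ct <- stage("compare",
                              rpd(map$values, ct$values, mask = profile$mask))
    if (!is.null(config$output_dir)) {
      utils::write.csv(result$rpd_vs_ct$per_plane,
                       file.path(config$output_dir, "rpd_vs_ct_per_plane.csv"),
                       row.names = FALSE)
      paths$rpd <- file.path(config$output_dir, "rpd_vs_ct_per_plane.csv")
    }
  }
  result$paths <- paths
  result
}

# stable md5 of the canonical YAML rendering of a config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
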