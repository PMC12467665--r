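# End-to-end pipeline: load or synthesise paired stacks, decompose, select,
# fuse across one ratio or a sweep, and write reproducible artifacts
# (fused PNGs, selection JSON, BPSO trace CSV, run manifest).

#' Assemble a validated run configuration
#'
#' @param conv_dir,ceus_dir directories of paired images (lexicographic
#'   order pairs them); both `NULL` to use the synthetic generator.
#' @param out_dir output directory (created if missing).
#' @param synthetic a [synthetic_params()] used when no directories are
#'   given.
#' @param bpso a [bpso_config()].
#' @param fusion a [fusion_spec()].
#' @param sweep optional numeric vector of fusion ratios; overrides
#'   `fusion$x` and writes one output folder per ratio.
#' @param centered_reconstruction use the mean-centred projection variant?
#' @param seed global seed; re-seeds the BPSO and generator configs so a
#'   run is a pure function of this configuration.
#' @return list of class `run_config`.
#' @export
run_config <- function(conv_dir = NULL, ceus_dir = NULL, out_dir = tempfile("flfsi_"),
                       synthetic = synthetic_params(),
                       bpso = bpso_config(),
                       fusion = fusion_spec(),
                       sweep = NULL,
                       centered_reconstruction = FALSE,
                       seed = 1L) {
  if (xor(is.null(conv_dir), is.null(ceus_dir))) {
    stop("provide both modality directories or neither", call. = FALSE)
  }
  if (!is.null(conv_dir)) {
    for (d in c(conv_dir, ceus_dir)) {
      if (!dir.exists(d)) stop("input directory does not exist: ", d, call. = FALSE)
    }
  }
  if (!is.null(sweep)) {
    if (any(sweep < 0 | sweep > 1)) stop("sweep ratios must lie in [0, 1]", call. = FALSE)
  }
  bpso$seed <- as.integer(seed)
  synthetic$seed <- as.integer(seed)
  structure(list(conv_dir = conv_dir, ceus_dir = ceus_dir, out_dir = out_dir,
                 synthetic = synthetic, bpso = bpso, fusion = fusion,
                 sweep = sweep,
                 centered_reconstruction = isTRUE(centered_reconstruction),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys: `conv_dir`, `ceus_dir`, `out_dir`, `seed`,
#' `sweep` (list of ratios), `centered_reconstruction`, and blocks
#' `synthetic:`, `bpso:`, `fusion:` whose keys match the corresponding
#' constructors. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("conv_dir", "ceus_dir", "out_dir", "seed", "sweep",
             "centered_reconstruction", "synthetic", "bpso", "fusion")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  args <- y[intersect(names(y), c("conv_dir", "ceus_dir", "out_dir", "seed",
                                  "sweep", "centered_reconstruction"))]
  if (!is.null(y$synthetic)) args$synthetic <- do.call(synthetic_params, y$synthetic)
  if (!is.null(y$bpso)) args$bpso <- do.call(bpso_config, y$bpso)
  if (!is.null(y$fusion)) {
    args$fusion <- do.call(fusion_spec, y$fusion)
  }
  if (!is.null(args$sweep)) args$sweep <- as.numeric(unlist(args$sweep))
  do.call(run_config, args)
}

load_pair_stacks <- function(config) {
  if (is.null(config$conv_dir)) {
    ds <- generate_dataset(config$synthetic)
    list(conv = ds$conv, ceus = ds$ceus, masks = ds$masks,
         source = "synthetic", manifest = ds$manifest)
  } else {
    list(conv = read_image_stack(config$conv_dir),
         ceus = read_image_stack(config$ceus_dir),
         masks = NULL, source = "directories", manifest = NULL)
  }
}

#' Run the full fusion pipeline
#'
#' Loads or synthesises the paired stacks, builds one basis and one
#' component selection per modality, reconstructs, and fuses at each
#' requested ratio. Writes, under `out_dir`: `fused_x<ratio>/pair_###.png`,
#' `selection.json` (B1/B2/B per modality, 1-based indices),
#' `bpso_trace.csv` (iteration, best fitness, cumulative evaluations, per
#' modality) and `manifest.json` (config echo, seeds, input content
#' hashes). Baseline modes skip the swarm and use top-k selection.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the selection sets, traces, output paths
#'   and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  data <- load_pair_stacks(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config$fusion
  ratios <- if (is.null(config$sweep)) spec$x else config$sweep

  stage <- function(stack, cfg, label) {
    basis <- projection_basis(stack, centered = config$centered_reconstruction)
    d <- basis_dim(basis)
    if (spec$mode == "flfsi") {
      sel <- select_components(stack, basis, cfg, m = min(spec$m, d))
      list(basis = basis, b1 = sel$b1, b2 = sel$b2, b = sel$b,
           trace = sel$bpso$trace, evaluations = sel$bpso$evaluations,
           label = label)
    } else {
      list(basis = basis, b1 = NULL, b2 = NULL,
           b = baseline_topk(basis, min(spec$top_k, d)),
           trace = NULL, evaluations = 0L, label = label)
    }
  }
  conv_stack <- data$conv
  ceus_stack <- data$ceus
  if (spec$mode == "gray_topk") {
    conv_stack <- image_stack(lapply(conv_stack, as_gray, replicate = TRUE))
    ceus_stack <- image_stack(lapply(ceus_stack, as_gray, replicate = TRUE))
  }
  cfg_ceus <- config$bpso
  cfg_ceus$seed <- config$bpso$seed + 1L
  conv_sel <- stage(conv_stack, config$bpso, "conv")
  ceus_sel <- stage(ceus_stack, cfg_ceus, "ceus")

  conv_rec <- reconstruct_stack(conv_stack, conv_sel$basis, conv_sel$b)
  ceus_rec <- reconstruct_stack(ceus_stack, ceus_sel$basis, ceus_sel$b)

  out_dirs <- character(0)
  for (x in ratios) {
    dir_x <- file.path(config$out_dir, sprintf("fused_x%.1f", x))
    dir.create(dir_x, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(conv_rec)) {
      write_image_png(fuse_images(conv_rec[[i]], ceus_rec[[i]], x),
                      file.path(dir_x, sprintf("pair_%03d.png", i)))
    }
    out_dirs <- c(out_dirs, dir_x)
  }

  sel_json <- list(
    conv = list(B1 = if (is.null(conv_sel$b1)) NULL else conv_sel$b1$indices,
                B2 = if (is.null(conv_sel$b2)) NULL else conv_sel$b2$indices,
                B = conv_sel$b$indices),
    ceus = list(B1 = if (is.null(ceus_sel$b1)) NULL else ceus_sel$b1$indices,
                B2 = if (is.null(ceus_sel$b2)) NULL else ceus_sel$b2$indices,
                B = ceus_sel$b$indices),
    indexing = "1-based")
  jsonlite::write_json(sel_json, file.path(config$out_dir, "selection.json"),
                       auto_unbox = FALSE, pretty = TRUE)

  if (!is.null(conv_sel$trace)) {
    tr <- rbind(
      data.frame(modality = "conv", iteration = seq_along(conv_sel$trace),
                 best_fitness = conv_sel$trace,
                 evaluations = seq_along(conv_sel$trace) * config$bpso$swarm_size),
      data.frame(modality = "ceus", iteration = seq_along(ceus_sel$trace),
                 best_fitness = ceus_sel$trace,
                 evaluations = seq_along(ceus_sel$trace) * config$bpso$swarm_size))
    utils::write.csv(tr, file.path(config$out_dir, "bpso_trace.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    source = data$source,
    seed = config$seed,
    n_pairs = length(data$conv),
    shape = c(attr(data$conv, "height"), attr(data$conv, "width"), 3L),
    mode = spec$mode,
    ratios = ratios,
    centered_reconstruction = config$centered_reconstruction,
    bpso = unclass(config$bpso),
    synthetic = if (data$source == "synthetic") unclass(config$synthetic) else NULL,
    selection_sizes = list(
      conv = list(B1 = length(sel_json$conv$B1), B2 = length(sel_json$conv$B2),
                  B = length(sel_json$conv$B)),
      ceus = list(B1 = length(sel_json$ceus$B1), B2 = length(sel_json$ceus$B2),
                  B = length(sel_json$ceus$B))),
    input_hashes = list(
      conv = vapply(data$conv, content_hash, character(1)),
      ceus = vapply(data$ceus, content_hash, character(1))),
    elapsed_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(selection = sel_json, conv = conv_sel, ceus = ceus_sel,
                 out_dirs = out_dirs, manifest = manifest,
                 masks = data$masks))
}

#' Compare the two BPSO variants on one seeded problem
#'
#' Runs the traditional and the improved variant on the same fitness
#' problem and seeds, and reports per-variant wall-clock per iteration,
#' evaluation counts and final fitness. Absolute durations are printed for
#' information only; the meaningful claims are relative (same problem
#' hash, equal evaluation budgets).
#'
#' @param stack an [image_stack()].
#' @param basis its `projection_basis` (built if `NULL`).
#' @param config a [bpso_config()]; the `variant` field is overridden.
#' @return data frame with one row per variant: `variant`, `seconds`,
#'   `seconds_per_iteration`, `evaluations`, `gbest_fitness`,
#'   `gbest_cardinality`, `problem_hash`.
#' @export
benchmark_variants <- function(stack, basis = NULL, config = bpso_config()) {
  if (is.null(basis)) basis <- projection_basis(stack)
  phash <- content_hash(unlist(lapply(stack, as.numeric)))
  rows <- lapply(c("traditional", "improved"), function(v) {
    cfg <- config
    cfg$variant <- v
    tm <- system.time(res <- run_bpso(stack, basis, cfg))[["elapsed"]]
    data.frame(variant = v, seconds = tm,
               seconds_per_iteration = tm / cfg$iterations,
               evaluations = res$evaluations,
               gbest_fitness = res$gbest_fitness,
               gbest_cardinality = sum(res$gbest),
               problem_hash = phash,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

mask_polygon <- function(mask, max_points = 40L) {
  h <- nrow(mask)
  w <- ncol(mask)
  cl <- grDevices::contourLines(x = seq_len(h), y = seq_len(w),
                                z = mask, levels = 0.5)
  if (length(cl) == 0L) return(NULL)
  lens <- vapply(cl, function(c1) length(c1$x), integer(1))
  c1 <- cl[[which.max(lens)]]
  # contourLines' x follows rows (image y), y follows columns (image x)
  px <- c1$y / w
  py <- c1$x / h
  if (length(px) > max_points) {
    keep <- unique(round(seq(1, length(px), length.out = max_points)))
    px <- px[keep]
    py <- py[keep]
  }
  cbind(px, py)
}

#' Export a stack and its masks as a YOLO-segmentation dataset
#'
#' Writes `images/pair_###.png` plus `labels/pair_###.txt`, each label line
#' being `class x1 y1 x2 y2 ...` with polygon vertices normalised to
#' `[0, 1]` (the boundary of the binary mask, traced at level 0.5).
#' Masks are also written as binary PNGs under `masks/`.
#'
#' @param stack an [image_stack()].
#' @param masks list of binary `H x W` matrices, one per image.
#' @param dir output directory.
#' @param class_id integer class written on each label line.
#' @return invisibly, the output directory.
#' @export
export_yolo <- function(stack, masks, dir, class_id = 0L) {
  if (length(stack) != length(masks)) {
    stop("need one mask per image", call. = FALSE)
  }
  for (sub in c("images", "labels", "masks")) {
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(stack)) {
    stem <- sprintf("pair_%03d", i)
    write_image_png(stack[[i]], file.path(dir, "images", paste0(stem, ".png")))
    png::writePNG(masks[[i]], file.path(dir, "masks", paste0(stem, ".png")))
    poly <- mask_polygon(masks[[i]])
    line <- if (is.null(poly)) character(0) else
      paste(class_id, paste(sprintf("%.6f", t(poly)), collapse = " "))
    writeLines(line, file.path(dir, "labels", paste0(stem, ".txt")))
  }
  invisible(dir)
}
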