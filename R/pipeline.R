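# End-to-end pipeline: offline stage (simulate styled motions, extract
# pose features, train the ConvRBM, embed, match similar frames, build
# the motion graph) followed by the online stage (pick a transition path
# for a style query and synthesize the blended motion). Every stochastic
# step is seeded from the single config seed, so a rerun with the same
# config is bit-identical.

#' Build a pipeline run configuration
#'
#' One declarative document holding every module default. Unknown keys
#' are rejected.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 42L,
    out_dir = tempfile("mocap_run_"),
    styles = c("walking", "running"),
    from = "walking", to = "running",
    n_joints = 32L, n_frames = 180L, frame_rate = 60,
    noise_sd = 0.5,
    interval = 1L, reference = "root",
    n_filters = 8L, kernel_width = 9L, input_mode = "dynamics",
    cd_k = 1L, lr = 1e-3, epochs = 3L, batch = 32L,
    threshold = "auto", threshold_prob = 0.15, exclusion = 10L,
    window = 30L, rotation_blend = "slerp")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop_mocap("unknown config keys: %s", paste(unknown, collapse = ", "))
  structure(utils::modifyList(defaults, overrides), class = "run_config")
}

#' Run the full offline + online pipeline
#'
#' Writes, under `config$out_dir`: the trained model (`model.json`), the
#' motion graph (`graph.json`), the matched pairs (`pairs.csv`), the
#' synthesized transition (`blend.bvh`) and a run report
#' (`report.json`) containing the fully resolved config and artifact
#' checksums. With `from == to` the pipeline short-circuits.
#'
#' @param config a `run_config` (see [pipeline_config()]).
#' @param quiet suppress progress messages.
#' @return the report, invisibly (list).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  report <- list(config = unclass(cfg), stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop_mocap("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    report$stages[[name]] <<- "ok"
    res
  }

  if (cfg$from == cfg$to) {
    report$result <- "no transition needed"
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    return(invisible(report))
  }

  sk <- stage("skeleton", gen_skeleton(cfg$n_joints, seed = cfg$seed))
  say("simulating %d styles", length(cfg$styles))
  motions <- stage("simulate", {
    out <- lapply(seq_along(cfg$styles), function(i)
      gen_motion(sk, style_spec(cfg$styles[i], noise_sd = cfg$noise_sd),
                 n_frames = cfg$n_frames, frame_rate = cfg$frame_rate,
                 seed = cfg$seed + i))
    names(out) <- cfg$styles
    out
  })
  feats <- stage("features", lapply(motions, pose_features,
                                    interval = cfg$interval,
                                    reference = cfg$reference))
  say("training ConvRBM")
  stats <- feature_stats(do.call(rbind, lapply(feats, `[[`, "point_cloud")))
  model <- stage("train", {
    m <- conv_rbm(n_filters = cfg$n_filters, kernel_width = cfg$kernel_width,
                  input_mode = cfg$input_mode, seed = cfg$seed)
    slabs <- unlist(lapply(feats, function(f)
      encode_slabs(m, f$point_cloud, stats)), recursive = FALSE)
    train_cd(m, slabs, k = cfg$cd_k, lr = cfg$lr, epochs = cfg$epochs,
             batch = cfg$batch, seed = cfg$seed)
  })
  write_rbm(model, file.path(cfg$out_dir, "model.json"))
  embs <- stage("encode", lapply(feats, function(f)
    encode(model, f$point_cloud, stats = stats)))
  thr <- stage("threshold", {
    if (identical(cfg$threshold, "auto"))
      similarity_threshold(do.call(rbind, lapply(embs, unclass)), cfg$threshold_prob)
    else as.numeric(cfg$threshold)
  })
  say("matching with threshold %.4g", thr)
  pairs <- stage("match", {
    p <- find_similar_frames(embs[[cfg$from]], embs[[cfg$to]], thr,
                             exclusion = cfg$exclusion)
    if (!nrow(p)) stop_mocap("no similar frames under threshold %.4g", thr)
    data.frame(seq_a = cfg$from, frame_a = p$frame_a,
               seq_b = cfg$to, frame_b = p$frame_b, distance = p$distance)
  })
  utils::write.csv(pairs, file.path(cfg$out_dir, "pairs.csv"), row.names = FALSE)
  mg <- stage("graph", build_graph(motions, pairs))
  write_graph(mg, file.path(cfg$out_dir, "graph.json"))
  path <- stage("select", {
    p <- select_transition(mg, cfg$from, cfg$to)
    if (!p$available) stop_mocap("no transition available")
    p
  })
  blend <- stage("synthesize",
                 synthesize(mg, path, motions,
                            transition_config(cfg$window, cfg$rotation_blend)))
  write_motion(sk, blend, file.path(cfg$out_dir, "blend.bvh"))
  report$result <- "ok"
  report$bottleneck <- path$bottleneck
  report$n_pairs <- nrow(pairs)
  report$output_frames <- nrow(blend$frames)
  arts <- c("model.json", "pairs.csv", "graph.json", "blend.bvh")
  report$artifacts <- stats::setNames(
    lapply(arts, function(a) unname(tools::md5sum(file.path(cfg$out_dir, a)))),
    arts)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
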