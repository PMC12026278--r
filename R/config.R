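# Structured run configuration and the command dispatcher behind the
# command-line entry point (inst/cli/foodseg.R). A run config is a nested
# key/value tree (YAML on disk); unknown keys are rejected with every
# offending key named, and each run writes its resolved configuration next
# to its outputs for provenance.

CONFIG_SCHEMA <- list(
  seed = NA, output_dir = NA, log_level = NA,
  data = c("dir", "num_classes", "canvas_side", "items_min", "items_max",
           "n_train", "n_test", "plate_radius_fraction", "noise_sd"),
  model = c("num_classes", "neck", "attention", "include_feature_head"),
  train = c("epochs", "batch_size", "base_lr", "momentum", "weight_decay",
            "poly_power", "side", "flip_prob", "checkpoint"),
  eval = c("side", "convention", "checkpoint", "split"),
  uncertainty = c("lambda_hat", "n_images", "side", "checkpoint"),
  nutrition = c("mask", "table", "margin"),
  complexity = c("side", "convention")
)

#' Validate a run configuration tree
#'
#' @param config nested list.
#' @return the config, invisibly; errors list every unknown key.
#' @export
validate_run_config <- function(config) {
  bad <- character()
  for (key in names(config)) {
    if (!key %in% names(CONFIG_SCHEMA)) {
      bad <- c(bad, key)
      next
    }
    sub <- CONFIG_SCHEMA[[key]]
    if (length(sub) > 1L || !is.na(sub[1L])) {
      unknown <- setdiff(names(config[[key]]), sub)
      if (length(unknown)) bad <- c(bad, paste0(key, ".", unknown))
    }
  }
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  invisible(config)
}

#' Read a YAML run configuration
#' @param path YAML file.
#' @param overrides named character vector of `section.key=value` overrides.
#' @export
read_run_config <- function(path, overrides = character()) {
  config <- yaml::read_yaml(path)
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    keys <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    val <- utils::type.convert(kv[2L], as.is = TRUE)
    if (length(keys) == 1L) config[[keys]] <- val
    else config[[keys[1L]]][[keys[2L]]] <- val
  }
  validate_run_config(config)
  config
}

cfg_get <- function(config, section, key, default) {
  v <- config[[section]][[key]]
  if (is.null(v)) default else v
}

#' Execute a pipeline command
#'
#' The single entry point the CLI wraps. All randomness derives from
#' `config$seed`; every run writes `resolved_config.yaml` into its output
#' directory.
#'
#' @param command one of generate-fixtures, train, eval, predict,
#'   complexity, uncertainty, nutrition, pareto.
#' @param config validated configuration list.
#' @return invisibly, a list of produced artifact paths / results.
#' @export
run_command <- function(command = c("generate-fixtures", "train", "eval",
                                    "predict", "complexity", "uncertainty",
                                    "nutrition", "pareto"),
                        config) {
  command <- match.arg(command)
  validate_run_config(config)
  out_dir <- config$output_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 0L
  yaml::write_yaml(c(list(command = command), config),
                   file.path(out_dir, "resolved_config.yaml"))
  data_dir <- cfg_get(config, "data", "dir", file.path(out_dir, "dataset"))
  K <- cfg_get(config, "model", "num_classes",
               cfg_get(config, "data", "num_classes", 4L))
  res <- switch(command,
    "generate-fixtures" = {
      spec <- scene_spec(
        num_classes = cfg_get(config, "data", "num_classes", 4L),
        seed = seed,
        items_per_scene = c(cfg_get(config, "data", "items_min", 1L),
                            cfg_get(config, "data", "items_max", 3L)),
        canvas_side = cfg_get(config, "data", "canvas_side", 128L),
        plate_radius_fraction = cfg_get(config, "data",
                                        "plate_radius_fraction", 0.42),
        noise_sd = cfg_get(config, "data", "noise_sd", 14))
      generate_dataset(spec, cfg_get(config, "data", "n_train", 8L),
                       cfg_get(config, "data", "n_test", 2L), data_dir)
    },
    "train" = {
      ds <- load_fixture_dataset(data_dir, K)
      model <- build_model(config_to_model(config, K), seed = seed)
      tc <- train_config(
        epochs = cfg_get(config, "train", "epochs", 100L),
        batch_size = cfg_get(config, "train", "batch_size", 8L),
        base_lr = cfg_get(config, "train", "base_lr", 0.05),
        momentum = cfg_get(config, "train", "momentum", 0.9),
        weight_decay = cfg_get(config, "train", "weight_decay", 1e-4),
        poly_power = cfg_get(config, "train", "poly_power", 0.9),
        seed = seed, side = cfg_get(config, "train", "side", 128L),
        flip_prob = cfg_get(config, "train", "flip_prob", 0.5))
      fit <- train_model(model, ds$train_samples, tc)
      ck <- cfg_get(config, "train", "checkpoint",
                    file.path(out_dir, "checkpoint.rds"))
      save_checkpoint(fit$model, ck)
      utils::write.csv(data.frame(iteration = seq_along(fit$loss) - 1L,
                                  loss = fit$loss, lr = fit$lr),
                       file.path(out_dir, "loss_trace.csv"), row.names = FALSE)
      list(checkpoint = ck, loss = fit$loss)
    },
    "eval" = {
      ds <- load_fixture_dataset(data_dir, K)
      model <- load_checkpoint(checkpoint_path(config, out_dir))
      samples <- if (cfg_get(config, "eval", "split", "test") == "train")
        ds$train_samples else ds$test_samples
      ev <- evaluate_model(model, samples,
                           side = cfg_get(config, "eval", "side", 128L),
                           convention = cfg_get(config, "eval", "convention",
                                                "skip"))
      jsonlite::write_json(list(miou = ev$miou, n_images = ev$n_images,
                                num_classes = ev$num_classes),
                           file.path(out_dir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      utils::write.csv(as.data.frame(ev$per_image),
                       file.path(out_dir, "per_image_iou.csv"),
                       row.names = FALSE)
      ev
    },
    "predict" = {
      ds <- load_fixture_dataset(data_dir, K)
      model <- load_checkpoint(checkpoint_path(config, out_dir))
      side <- cfg_get(config, "eval", "side", 128L)
      dir.create(file.path(out_dir, "predictions"), showWarnings = FALSE)
      paths <- vapply(seq_along(ds$test_samples), function(i) {
        pr <- preprocess(ds$test_samples[[i]], side)
        lab <- predict_labels(model_forward(model, pr$image))
        p <- file.path(out_dir, "predictions", sprintf("pred_%03d.png", i))
        write_mask(lab, ds$palette, p)
        p
      }, "")
      list(predictions = paths)
    },
    "complexity" = {
      rep <- complexity_report(config_to_model(config, K),
                               side = cfg_get(config, "complexity", "side", 512L),
                               convention = cfg_get(config, "complexity",
                                                    "convention", "published"))
      jsonlite::write_json(list(parameters = rep$parameters, macs = rep$macs,
                                side = rep$side, convention = rep$convention,
                                per_layer = rep$per_layer),
                           file.path(out_dir, "complexity.json"),
                           auto_unbox = TRUE, digits = NA)
      rep
    },
    "uncertainty" = {
      ds <- load_fixture_dataset(data_dir, K)
      model <- load_checkpoint(checkpoint_path(config, out_dir))
      side <- cfg_get(config, "uncertainty", "side", 128L)
      lh <- cfg_get(config, "uncertainty", "lambda_hat", 0.01)
      nim <- min(cfg_get(config, "uncertainty", "n_images", 2L),
                 length(ds$test_samples))
      dir.create(file.path(out_dir, "uncertainty"), showWarnings = FALSE)
      for (i in seq_len(nim)) {
        pr <- preprocess(ds$test_samples[[i]], side)
        cp <- conformal_predict(model, pr$image, lh)
        png::writePNG(matrix(cp$heatmap$summary, side, side),
                      file.path(out_dir, "uncertainty",
                                sprintf("summary_%03d.png", i)))
        saveRDS(cp$heatmap$V, file.path(out_dir, "uncertainty",
                                        sprintf("V_%03d.rds", i)))
      }
      list(dir = file.path(out_dir, "uncertainty"), lambda_hat = lh)
    },
    "nutrition" = {
      pal_path <- file.path(data_dir, "palette.json")
      pal <- if (file.exists(pal_path)) read_palette(pal_path) else NULL
      tab <- read_composition(cfg_get(config, "nutrition", "table",
                                      file.path(data_dir, "composition.csv")))
      mask_path <- config$nutrition$mask
      if (is.null(mask_path)) stop("nutrition.mask is required")
      labels <- if (is.null(pal)) {
        a <- png::readPNG(mask_path)
        m <- round(a * 255); storage.mode(m) <- "integer"; m
      } else read_mask(mask_path, pal)
      est <- nutrients_from_mask(labels, tab, num_classes = K,
                                 margin = cfg_get(config, "nutrition",
                                                  "margin", 0.05),
                                 palette = pal)
      utils::write.csv(est, file.path(out_dir, "nutrients.csv"),
                       row.names = FALSE)
      jsonlite::write_json(as.list(attr(est, "totals")),
                           file.path(out_dir, "nutrient_totals.json"),
                           auto_unbox = TRUE, digits = NA)
      est
    },
    "pareto" = {
      pts <- utils::read.csv(file.path(data_dir, "pareto_points.csv"),
                             stringsAsFactors = FALSE)
      front <- pareto_front(pts)
      utils::write.csv(front, file.path(out_dir, "pareto_front.csv"),
                       row.names = FALSE)
      front
    })
  invisible(res)
}

config_to_model <- function(config, K) {
  model_config(K,
               neck = cfg_get(config, "model", "neck", "cwaspp"),
               attention = cfg_get(config, "model", "attention", "se"),
               include_feature_head = cfg_get(config, "model",
                                              "include_feature_head", TRUE))
}

checkpoint_path <- function(config, out_dir) {
  cfg_get(config, "eval", "checkpoint",
          cfg_get(config, "train", "checkpoint",
                  file.path(out_dir, "checkpoint.rds")))
}

load_fixture_dataset <- function(dir, num_classes) {
  pal <- read_palette(file.path(dir, "palette.json"))
  if (nrow(pal) != num_classes)
    stop("palette has ", nrow(pal), " classes but num_classes = ", num_classes)
  tr <- read_manifest(file.path(dir, "manifest_train.csv"), "train", num_classes)
  te <- read_manifest(file.path(dir, "manifest_test.csv"), "test", num_classes)
  list(palette = pal,
       train_samples = load_samples(tr, pal),
       test_samples = load_samples(te, pal))
}
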