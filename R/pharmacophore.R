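# Pharmacophore model container and serialization.  A model is a set of
# typed features (center, radius, essential flag) plus excluded-volume
# spheres marking receptor-occupied space.

#' Construct a pharmacophore model
#'
#' @param name Model name.
#' @param features Tibble with columns `label`, `kind`, `x`, `y`, `z`,
#'   `radius`, `essential`, and optional `annotation`.
#' @param exclusions Tibble with columns `x`, `y`, `z`, `radius`
#'   (excluded-volume spheres).
#' @param provenance Free-form provenance note (source complexes etc.).
#' @return An object of class `ph4_model`.
#' @export
ph4_model <- function(name, features, exclusions = NULL, provenance = "") {
  features <- tibble::as_tibble(features)
  need <- c("label", "kind", "x", "y", "z", "radius", "essential")
  miss <- setdiff(need, names(features))
  if (length(miss)) abort(sprintf("model features missing columns: %s",
                                  paste(miss, collapse = ", ")))
  if (!"annotation" %in% names(features)) features$annotation <- ""
  if (anyDuplicated(features$label)) abort("feature labels must be unique")
  if (any(!features$kind %in% FEATURE_KINDS)) abort("unknown feature kind")
  if (any(features$radius <= 0)) abort("feature radius must be > 0")
  if (sum(features$essential) < 3) {
    abort("a model needs at least 3 essential features for well-posed matching")
  }
  if (is.null(exclusions)) {
    exclusions <- tibble::tibble(x = numeric(), y = numeric(),
                                 z = numeric(), radius = numeric())
  }
  exclusions <- tibble::as_tibble(exclusions)
  if (nrow(exclusions) && any(exclusions$radius <= 0)) {
    abort("exclusion sphere radius must be > 0")
  }
  structure(list(name = name, features = features,
                 exclusions = exclusions, provenance = provenance),
            class = "ph4_model")
}

#' @export
print.ph4_model <- function(x, ...) {
  cat(sprintf("<ph4_model> %s: %d features (%d essential), %d excluded volumes\n",
              x$name, nrow(x$features), sum(x$features$essential),
              nrow(x$exclusions)))
  tab <- x$features
  cat(paste0(sprintf("  %-8s %-9s (%6.2f,%6.2f,%6.2f) r=%.2f %s %s",
                     tab$label, tab$kind, tab$x, tab$y, tab$z, tab$radius,
                     ifelse(tab$essential, "essential", "optional "),
                     tab$annotation), collapse = "\n"), "\n")
  invisible(x)
}

is_ph4_model <- function(x) inherits(x, "ph4_model")

model_coords <- function(model, essential_only = FALSE) {
  f <- model$features
  if (essential_only) f <- f[f$essential, , drop = FALSE]
  as.matrix(f[, c("x", "y", "z")])
}

#' Inter-feature distance matrix
#'
#' Pairwise Euclidean distances between feature centers, in Angstrom;
#' invariant under rigid motion of the model.
#'
#' @param model A [ph4_model()].
#' @return Symmetric matrix with zero diagonal, labelled by feature.
#' @export
interfeature_distances <- function(model) {
  stopifnot(is_ph4_model(model))
  m <- as.matrix(stats::dist(model_coords(model)))
  dimnames(m) <- list(model$features$label, model$features$label)
  m
}

#' Write a pharmacophore model to JSON
#'
#' Schema: `{"name", "points": [{"kind","x","y","z","radius",
#' "essential","label","annotation"}], "exclusions": [{"x","y","z",
#' "radius"}], "provenance"}`. The round-trip is field-identical.
#'
#' @param model A [ph4_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ph4_json <- function(model, path) {
  stopifnot(is_ph4_model(model))
  obj <- list(
    name = model$name,
    points = lapply(seq_len(nrow(model$features)), function(k) {
      f <- model$features[k, ]
      list(kind = f$kind, x = f$x, y = f$y, z = f$z, radius = f$radius,
           essential = f$essential, label = f$label, annotation = f$annotation)
    }),
    exclusions = lapply(seq_len(nrow(model$exclusions)), function(k) {
      e <- model$exclusions[k, ]
      list(x = e$x, y = e$y, z = e$z, radius = e$radius)
    }),
    provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a pharmacophore model from JSON
#'
#' @param path Path to a model in the package schema (see
#'   [write_ph4_json()]).
#' @return A [ph4_model()].
#' @export
read_ph4_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path)
  features <- dplyr::bind_rows(lapply(obj$points, function(p) {
    tibble::tibble(label = p$label, kind = p$kind, x = p$x, y = p$y, z = p$z,
                   radius = p$radius, essential = isTRUE(p$essential),
                   annotation = p$annotation %||% "")
  }))
  exclusions <- if (length(obj$exclusions)) {
    dplyr::bind_rows(lapply(obj$exclusions, function(e)
      tibble::tibble(x = e$x, y = e$y, z = e$z, radius = e$radius)))
  } else NULL
  ph4_model(obj$name, features, exclusions, obj$provenance %||% "")
}

#' Read a Pharmer-style points JSON
#'
#' Interoperability reader for the `{"points": [{"name","x","y","z",
#' "radius","enabled"}]}` dialect used by online pharmacophore search
#' servers. Feature names are mapped onto the package kinds
#' (`Aromatic` -> ARO, `HydrogenAcceptor` -> ACC, `HydrogenDonor` ->
#' DON, `Hydrophobic` -> HYD); `ExclusionSphere` points become excluded
#' volumes; disabled points are dropped.
#'
#' @param path Path to the JSON file.
#' @param name Model name (default: file base name).
#' @return A [ph4_model()] with all features marked essential.
#' @export
read_pharmer_json <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path)
  name <- name %||% sub("\\.json$", "", basename(path))
  kind_map <- c(Aromatic = "ARO", HydrogenAcceptor = "ACC",
                HydrogenDonor = "DON", Hydrophobic = "HYD")
  feats <- list(); excl <- list()
  for (p in obj$points) {
    if (!isTRUE(p$enabled %||% TRUE)) next
    if (identical(p$name, "ExclusionSphere")) {
      excl[[length(excl) + 1]] <- tibble::tibble(
        x = p$x, y = p$y, z = p$z, radius = p$radius %||% 1)
    } else if (p$name %in% names(kind_map)) {
      feats[[length(feats) + 1]] <- tibble::tibble(
        label = paste0(kind_map[[p$name]], length(feats) + 1),
        kind = kind_map[[p$name]], x = p$x, y = p$y, z = p$z,
        radius = p$radius %||% 1, essential = TRUE, annotation = "")
    }
  }
  if (!length(feats)) abort("no mappable feature points in file")
  ph4_model(name, dplyr::bind_rows(feats),
            if (length(excl)) dplyr::bind_rows(excl) else NULL,
            provenance = sprintf("imported from %s", basename(path)))
}

#' Load a packaged pharmacophore model reconstruction
#'
#' The package ships reconstructions of the two selected kinase models
#' (a 5-feature VEGFR2 model with 378 excluded volumes and a 5-feature
#' FAK model with 68 excluded volumes). Their feature inventories follow
#' the published descriptions; the 3D geometry is a documented synthetic
#' reconstruction (the original coordinates were never published), so
#' these are suitable as realistic engine inputs, not as the canonical
#' published models.
#'
#' @param target `"vegfr2"` or `"fak"`.
#' @return A [ph4_model()].
#' @export
load_kinase_model <- function(target = c("vegfr2", "fak")) {
  target <- match.arg(target)
  fn <- c(vegfr2 = "vegfr2_ph4_109_synthetic.json",
          fak = "fak_ph4_12_synthetic.json")[[target]]
  read_ph4_json(system.file("extdata", fn, package = "pharmscreen"))
}
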