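#' Read and write volumes as ASCII NRRD
#'
#' A minimal NRRD implementation covering the subset this package writes:
#' 3D arrays, ascii or gzip-free raw-text encoding, `spacings`/`space
#' directions` and `space origin` metadata. Values are stored fastest-first
#' along the first array dimension, matching R's column-major layout.
#'
#' @param path file path ending in `.nrrd`.
#' @param vol an `image_volume` or `binary_mask`.
#' @return `read_nrrd` returns an `image_volume`; `write_nrrd` returns
#'   `path` invisibly.
#' @export
write_nrrd <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  hdr <- c(
    "NRRD0004",
    "# produced by radrobust",
    "type: double",
    "dimension: 3",
    "space: left-posterior-superior",
    sprintf("sizes: %d %d %d", d[1], d[2], d[3]),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            vol$origin[1], vol$origin[2], vol$origin[3]),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: ascii",
    ""
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(format(as.vector(vol$data), digits = 17, trim = TRUE,
                          scientific = TRUE), collapse = " "), con)
  invisible(path)
}

#' @rdname write_nrrd
#' @param as_mask binarize (> 0) and return a `binary_mask`.
#' @export
read_nrrd <- function(path, as_mask = FALSE) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "NRRD")) stop("unsupported format: not a NRRD file")
  blank <- which(lines == "")[1]
  if (is.na(blank)) stop("malformed NRRD: no header terminator")
  hdr <- lines[2:(blank - 1)]
  hdr <- hdr[!startsWith(hdr, "#")]
  fields <- list()
  for (ln in hdr) {
    kv <- regmatches(ln, regexpr(": ", ln), invert = TRUE)[[1]]
    if (length(kv) == 2) fields[[kv[1]]] <- kv[2]
  }
  enc <- tolower(fields[["encoding"]] %||% "ascii")
  if (!enc %in% c("ascii", "txt", "text")) {
    stop("unsupported format: only ascii NRRD encoding is supported")
  }
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  if (length(sizes) != 3L) stop("unsupported format: only 3D NRRD supported")
  parse_vectors <- function(s) {
    m <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(m, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_vectors(fields[["space directions"]])
    spacing <- vapply(dirs, function(v) sqrt(sum(v^2)), 0)
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    spacing <- c(1, 1, 1)
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]])) {
    origin <- parse_vectors(fields[["space origin"]])[[1]]
  }
  vals <- scan(text = paste(lines[(blank + 1):length(lines)], collapse = " "),
               what = double(), quiet = TRUE)
  if (length(vals) != prod(sizes)) stop("malformed NRRD: value count mismatch")
  arr <- array(vals, dim = sizes)
  if (as_mask) binary_mask(arr, spacing, origin) else image_volume(arr, spacing, origin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a co-registered image/mask pair
#'
#' Loads both volumes, binarizes the mask at > 0, and enforces grid
#' compatibility (identical dimensions and spacing).
#'
#' @param image_path,mask_path paths to ASCII NRRD files.
#' @return list with elements `image` (`image_volume`) and `mask`
#'   (`binary_mask`).
#' @export
read_volume_pair <- function(image_path, mask_path) {
  image <- read_nrrd(image_path)
  mask <- read_nrrd(mask_path, as_mask = TRUE)
  stopifnot_same_grid(image, mask)
  list(image = image, mask = mask)
}

#' Write experiment results with a reproducibility manifest
#'
#' Writes the per-split model evaluation records as tidy CSV, the threshold
#' group comparisons as JSON, and a manifest holding the configuration hash,
#' seed and package version, sufficient to replay the run.
#'
#' @param records data.frame of model evaluation records (one row per
#'   split x threshold x classifier).
#' @param comparisons list or data.frame of paired-test group comparisons.
#' @param out_dir output directory (created if needed).
#' @param config the run configuration list used to produce `records`.
#' @return the manifest list, invisibly.
#' @export
write_results <- function(records, comparisons, out_dir, config = list()) {
  if (is.null(records) || nrow(records) == 0L) stop("no records to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rec_path <- file.path(out_dir, "model_eval_records.csv")
  utils::write.csv(records, rec_path, row.names = FALSE)
  cmp_path <- file.path(out_dir, "group_comparisons.json")
  jsonlite::write_json(comparisons, cmp_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "radrobust",
    version = as.character(utils::packageVersion("radrobust")),
    config_hash = config_hash(config),
    seed = config$seed %||% NA,
    n_records = nrow(records),
    files = c(basename(rec_path), basename(cmp_path)),
    config = config
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Stable hash of a configuration list: serialize deterministically to JSON
# and fold into a hex digest (dependency-free FNV-1a over the UTF-8 bytes).
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(json)))
  h1 <- 2166136261 %% 2^31; h2 <- 0x811C9; p <- 16777619
  for (b in bytes) {
    h1 <- ((bitwXor(h1, b)) * p) %% 2^31
    h2 <- ((h2 * 31) + b) %% 2^31
  }
  sprintf("%08x%08x", h1, h2)
}

#' Write a phantom cohort to disk
#'
#' Images and masks as ASCII NRRD, outcomes and feature-truth tables as CSV,
#' and a JSON manifest naming every file plus the generator arguments.
#'
#' @param cohort a `phantom_cohort` from [generate_phantom_cohort()].
#' @param out_dir output directory.
#' @return manifest list, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort$patients, function(p) {
    ip <- file.path(out_dir, paste0(p$id, "_image.nrrd"))
    mp <- file.path(out_dir, paste0(p$id, "_mask.nrrd"))
    write_nrrd(p$image, ip)
    write_nrrd(p$mask, mp)
    list(id = p$id, image = basename(ip), mask = basename(mp))
  })
  utils::write.csv(cohort$outcomes, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(patients = entries, params = cohort$params,
                   outcomes = "outcomes.csv", truth = "truth.csv")
  jsonlite::write_json(manifest, file.path(out_dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
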