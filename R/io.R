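# Model checkpoints: a single-file format holding a JSON header (version,
# model type, configuration, seed, parameter names and shapes), the
# parameter arrays as little-endian float32 in header order, and an md5
# content hash of the parameter bytes.

.CHK_MAGIC <- "EACP"

# flatten a parameter tree into named arrays (paths joined with '/')
.flatten_params <- function(tree, prefix = "") {
  if (is.list(tree)) {
    out <- list()
    nms <- names(tree) %||% as.character(seq_along(tree))
    if (is.null(names(tree))) nms <- as.character(seq_along(tree))
    for (i in seq_along(tree)) {
      key <- if (nzchar(prefix)) paste(prefix, nms[i], sep = "/") else nms[i]
      out <- c(out, .flatten_params(tree[[i]], key))
    }
    out
  } else {
    stats::setNames(list(tree), prefix)
  }
}

.assign_path <- function(tree, path, value) {
  parts <- strsplit(path, "/")[[1]]
  expr <- tree
  if (length(parts) == 1) {
    tree[[parts]] <- value
    return(tree)
  }
  idx <- suppressWarnings(as.integer(parts[1]))
  key <- if (!is.na(idx)) idx else parts[1]
  tree[[key]] <- .assign_path(tree[[key]],
                              paste(parts[-1], collapse = "/"), value)
  tree
}

#' Write a model checkpoint
#'
#' Single-file binary format: 4-byte magic, little-endian int32 header
#' length, a JSON header (format version, model type, configuration, seed,
#' parameter names and shapes, md5 of the parameter bytes), then the
#' parameter arrays as little-endian float32 in header order.
#'
#' @param model an `ea_encoder` or `ea_aligner`.
#' @param path output file.
#' @return the md5 content hash, invisibly.
#' @export
writeCheckpoint <- function(model, path) {
  type <- if (inherits(model, "ea_encoder")) "encoder"
          else if (inherits(model, "ea_aligner")) "aligner"
          else stop("unsupported model class")
  params <- if (type == "encoder") model$params else model$heads[c("M", "G")]
  flat <- .flatten_params(params)
  # parameter bytes first, to hash them
  tmp <- tempfile()
  con <- file(tmp, "wb")
  for (arr in flat)
    writeBin(as.numeric(arr), con, size = 4, endian = "little")
  close(con)
  hash <- unname(tools::md5sum(tmp))
  cfg <- if (type == "encoder") unclass(model$config) else
    list(d = model$d, backend = model$backend,
         n_layers = model$heads$config$n_layers,
         width = model$heads$config$width,
         kernel = model$heads$config$kernel,
         seed = model$heads$config$seed,
         temperature = model$smoothing@temperature,
         border_mode = model$smoothing@border_mode,
         mu_on_gaps = model$smoothing@mu_on_gaps)
  header <- jsonlite::toJSON(list(
    format_version = 1L, model_type = type, config = cfg,
    params = lapply(flat, function(a) as.integer(dim(a) %||% length(a))),
    hash = hash), auto_unbox = TRUE)
  hbytes <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.CHK_MAGIC, con, nchars = 4, eos = NULL)
  writeBin(length(hbytes), con, size = 4, endian = "little")
  writeBin(hbytes, con)
  writeBin(readBin(tmp, "raw", file.size(tmp)), con)
  unlink(tmp)
  invisible(hash)
}

#' Read a model checkpoint
#'
#' @param path file written by [writeCheckpoint()].
#' @return the reconstructed model (parameters stored as float32, so
#'   round-tripped values are float32-exact).
#' @export
readCheckpoint <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, .CHK_MAGIC)) stop("not a checkpoint file: ", path)
  hlen <- readBin(con, "integer", 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  flat <- list()
  for (nm in names(header$params)) {
    dm <- header$params[[nm]]
    vals <- readBin(con, "numeric", prod(dm), size = 4, endian = "little")
    flat[[nm]] <- if (length(dm) > 1) array(vals, dim = dm) else vals
  }
  cfg <- header$config
  if (header$model_type == "encoder") {
    model <- newEncoder(encoderConfig(
      n_layers = cfg$n_layers, n_heads = cfg$n_heads, d_in = cfg$d_in,
      ff_dim = cfg$ff_dim, out_dim = cfg$out_dim, dropout = cfg$dropout,
      seed = cfg$seed))
    for (nm in names(flat))
      model$params <- .assign_path(model$params, nm, flat[[nm]])
  } else {
    model <- newAligner(
      d = cfg$d, n_layers = cfg$n_layers, width = cfg$width,
      kernel = cfg$kernel, backend = cfg$backend,
      smoothing = SmoothingConfig(cfg$temperature, cfg$border_mode,
                                  cfg$mu_on_gaps),
      seed = cfg$seed)
    heads <- model$heads[c("M", "G")]
    for (nm in names(flat)) heads <- .assign_path(heads, nm, flat[[nm]])
    model$heads$M <- heads$M
    model$heads$G <- heads$G
  }
  model
}

#' Read a pair-label table
#'
#' TSV with columns `id_a`, `id_b`, `label`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b", "label") %in% names(df)))
  df
}
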