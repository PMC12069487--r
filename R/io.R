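#' Write and read trajectories as CSV
#'
#' Plain-text round trip at 17 significant digits (lossless for doubles).
#' The header is `time,u_0,...,u_N` for full trajectories and
#' `time,mu_0,...,mu_K` for moment trajectories; the kind is recovered
#' from the header on read.  Ragged rows produce a structured parse
#' error naming the offending row.
#'
#' @param traj A [trajectory()].
#' @param path File path.
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns a [trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  header <- paste(c("time", colnames(traj$states)), collapse = ",")
  rows <- apply(cbind(traj$times, traj$states), 1, function(x) {
    paste(sprintf("%.17g", x), collapse = ",")
  })
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    stop("empty trajectory file: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (header[1] != "time" || length(header) < 2L) {
    stop("malformed trajectory header in ", path,
         ": expected 'time,u_0,...' or 'time,mu_0,...'", call. = FALSE)
  }
  kind <- if (all(grepl("^u_[0-9]+$", header[-1]))) {
    "full"
  } else if (all(grepl("^mu_[0-9]+$", header[-1]))) {
    "moments"
  } else {
    stop("malformed trajectory header in ", path,
         ": state columns must all be u_<j> or all mu_<k>", call. = FALSE)
  }
  n_col <- length(header)
  body <- lines[-1]
  if (length(body) == 0L) {
    return(trajectory(numeric(0),
                      matrix(numeric(0), 0, n_col - 1L), kind = kind))
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(fields)
  if (any(lens != n_col)) {
    bad <- which(lens != n_col)[1]
    stop("ragged trajectory row ", bad + 1L, " in ", path, ": expected ",
         n_col, " fields, found ", lens[bad], call. = FALSE)
  }
  vals <- matrix(as.numeric(unlist(fields)), ncol = n_col, byrow = TRUE)
  if (anyNA(vals)) {
    stop("non-numeric field in trajectory file ", path, call. = FALSE)
  }
  trajectory(vals[, 1], vals[, -1, drop = FALSE], kind = kind)
}

#' Model configuration files
#'
#' A structured model serialises to a JSON object
#' `{"N": int, "r": [...], "rho": [...], "d": [...], "e": [...],
#' "b": [...], "w": [...], "g0": float}` with coefficient arrays
#' ascending in the state index.  Files ending in `.yaml`/`.yml` use the
#' same schema in YAML.  The round trip is the identity on coefficient
#' lists.
#'
#' @param model A [structured_model()].
#' @param path File path; the extension selects JSON (default) or YAML.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` a [structured_model()].
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "structured_model"))
  obj <- list(N = model$N, r = model$r, rho = model$rho, d = model$d,
              e = model$e, b = model$b, w = model$w, g0 = model$g0)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 17L)
  } else {
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                                null = "null"), path)
  }
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(obj$N)) {
    stop("model config ", path, " lacks the required field N", call. = FALSE)
  }
  grab <- function(nm) {
    v <- obj[[nm]]
    if (is.null(v)) numeric(0) else as.numeric(v)
  }
  structured_model(N = obj$N, rho = grab("rho"), d = grab("d"),
                   e = grab("e"), b = grab("b"), w = grab("w"),
                   r = grab("r"),
                   g0 = if (is.null(obj$g0)) 0 else as.numeric(obj$g0))
}

# FNV-1a hash of a model's canonical JSON, for reproducibility logging.
model_hash <- function(model) {
  txt <- as.character(jsonlite::toJSON(
    list(N = model$N, r = model$r, rho = model$rho, d = model$d,
         e = model$e, b = model$b, w = model$w, g0 = model$g0),
    auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (byte in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), byte)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
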