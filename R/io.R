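# File formats: JSON force fields and run configurations, TSV iteration
# logs. Indices in files are 1-based sorted tuples (spectroscopic
# convention); reduced constants are stored in cm^-1, unreduced raw
# derivatives in Hartree atomic units.

#' Write a force field to JSON
#'
#' @param ff a \code{\link{force_field}}.
#' @param path output file.
#' @param meta optional named list stored verbatim under \code{"meta"}
#'   (e.g. sampler seed and regimes).
#' @return \code{path}, invisibly.
#' @export
write_force_field <- function(ff, path, meta = NULL) {
  fc <- list()
  for (nm in names(ff$phi)) {
    blk <- ff$phi[[nm]]
    for (r in seq_len(nrow(blk$idx))) {
      fc[[length(fc) + 1L]] <- list(order = as.integer(nm),
                                    indices = as.integer(blk$idx[r, ]),
                                    value_cm1 = blk$val[r],
                                    reduced = TRUE)
    }
  }
  obj <- list(L = ff$L, frequencies_cm1 = ff$w, force_constants = fc)
  if (!is.null(ff$coriolis)) {
    obj$coriolis <- list(B_cm1 = ff$coriolis$B,
                         xi = lapply(ff$coriolis$xi, function(m) unname(as.matrix(m))))
  }
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a force field from JSON
#'
#' Entries flagged \code{"reduced": false} must carry \code{value_au}
#' (the raw PES derivative in atomic units) and are reduced by the
#' frequency factors on load; reduced entries carry \code{value_cm1}.
#'
#' @param path JSON file following the schema written by
#'   \code{\link{write_force_field}}.
#' @return a \code{\link{force_field}}.
#' @export
read_force_field <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  known <- c("L", "frequencies_cm1", "force_constants", "coriolis", "meta")
  extra <- setdiff(names(obj), known)
  if (length(extra)) stop("unknown force-field keys: ", paste(extra, collapse = ", "))
  w <- as.numeric(unlist(obj$frequencies_cm1))
  if (!is.null(obj$L) && obj$L != length(w)) {
    stop("declared L does not match the number of frequencies")
  }
  w_au <- w * CM1_TO_HARTREE
  acc <- list()
  for (e in obj$force_constants) {
    nu <- as.integer(e$order)
    idx <- sort(as.integer(unlist(e$indices)))
    if (length(idx) != nu) stop("index tuple length does not match order ", nu)
    reduced <- isTRUE(e$reduced) || is.null(e$reduced)
    val <- if (reduced) {
      as.numeric(e$value_cm1)
    } else {
      if (is.null(e$value_au)) stop("unreduced entries need value_au")
      reduce_constants(matrix(idx, 1L), as.numeric(e$value_au), w_au) /
        CM1_TO_HARTREE
    }
    key <- as.character(nu)
    acc[[key]] <- rbind(acc[[key]], c(idx, val))
  }
  coriolis <- NULL
  if (!is.null(obj$coriolis)) {
    xi <- lapply(obj$coriolis$xi, function(m) {
      do.call(rbind, lapply(m, function(row) as.numeric(unlist(row))))
    })
    coriolis <- list(B = as.numeric(unlist(obj$coriolis$B_cm1)), xi = xi)
  }
  force_field(w, phi = acc, coriolis = coriolis)
}

#' Write / read a training configuration
#'
#' JSON round trip is lossless; unknown keys in the file are rejected.
#'
#' @param cfg a \code{\link{training_config}}.
#' @param path JSON file.
#' @return \code{path} / the reconstructed \code{training_config}.
#' @export
write_training_config <- function(cfg, path) {
  obj <- unclass(cfg)
  obj$ns_schedule <- apply(cfg$ns_schedule, 1L, as.list, simplify = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_training_config
#' @export
read_training_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(training_config))
  extra <- setdiff(names(obj), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  obj$ns_schedule <- matrix(as.integer(as.matrix(obj$ns_schedule)), ncol = 2L)
  do.call(training_config, obj)
}

#' Write an iteration log as TSV
#'
#' @param log the per-iteration data frame of \code{\link{run_ground}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_iteration_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
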