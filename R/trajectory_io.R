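# Sidecar path convention: <file>.meta.json next to the CSV.
.sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

# Small FNV-1a hash over a character serialization; used to stamp the
# generating configuration into the sidecar.
.config_hash <- function(x) {
  s <- paste(vapply(x, function(v) paste(format(v, digits = 15),
                                         collapse = ","), character(1)),
             collapse = ";")
  h <- 216613626
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Write a trajectory pair to a CSV file with a JSON sidecar
#'
#' The CSV holds one row per (time sample, agent) with columns
#' `t, agent_id, x, y, phi, phi_dot, s` at 15 significant digits; the
#' sidecar `<file>.meta.json` records class, seed, dt, arena, via points
#' and a hash of the generating configuration, so a written pair reads
#' back field-exact.
#'
#' @param pair a `trajectory_pair` (see [generate_pair()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(pair, path) {
  if (!inherits(pair, "trajectory_pair")) stop("pair must be a trajectory_pair")
  if (length(pair$t) == 0L) stop("refusing to write an empty trajectory")
  one <- function(id, df) data.frame(t = pair$t, agent_id = id, df)
  df <- rbind(one(1L, pair$agent1), one(2L, pair$agent2))
  df <- df[order(df$t, df$agent_id), ]
  num <- vapply(df[c("t", "x", "y", "phi", "phi_dot", "s")],
                function(col) sprintf("%.15g", col),
                character(nrow(df)))
  out <- data.frame(t = num[, "t"], agent_id = df$agent_id,
                    x = num[, "x"], y = num[, "y"], phi = num[, "phi"],
                    phi_dot = num[, "phi_dot"], s = num[, "s"])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta <- list(class_name = pair$class_name, seed = pair$seed,
               dt = pair$dt, arena = pair$arena,
               via_points = unname(apply(pair$via_points, 1, as.numeric,
                                         simplify = FALSE)),
               config_hash = .config_hash(list(pair$class_name, pair$seed,
                                               pair$dt, pair$arena)))
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trajectory pair written by [write_trajectory()]
#'
#' Rows are canonically re-sorted by `(t, agent_id)` (a stable sort, so
#' shuffled files reconstruct the identical pair), required columns and
#' a strictly increasing common time grid are checked, and the
#' reconstructed pair is passed through [validate_trajectory_pair()].
#'
#' @param path CSV path; the `<file>.meta.json` sidecar must be present.
#' @return A `trajectory_pair`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "agent_id", "x", "y", "phi", "s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trajectory file is missing column(s): ",
         paste(missing, collapse = ", "))
  if (!"phi_dot" %in% names(df)) df$phi_dot <- 0
  if (nrow(df) == 0L) stop("trajectory file has no data rows")
  df <- df[order(df$t, df$agent_id, method = "radix"), ]
  a1 <- df[df$agent_id == 1L, ]
  a2 <- df[df$agent_id == 2L, ]
  if (nrow(a1) == 0L || nrow(a2) == 0L)
    stop("trajectory file must contain rows for agent_id 1 and 2")
  if (nrow(a1) != nrow(a2) || any(a1$t != a2$t))
    stop("agents must share one common time grid (truncated file?)")
  if (any(diff(a1$t) <= 0)) stop("time grid must be strictly increasing")
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) stop("missing metadata sidecar: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  cols <- c("x", "y", "phi", "phi_dot", "s")
  via <- meta$via_points
  if (is.list(via)) via <- do.call(rbind, via)
  pair <- structure(list(
    class_name = meta$class_name,
    t = a1$t,
    agent1 = a1[cols], agent2 = a2[cols],
    via_points = matrix(as.numeric(via), ncol = 2),
    seed = as.integer(meta$seed), dt = as.numeric(meta$dt),
    arena = as.numeric(meta$arena)),
    class = "trajectory_pair")
  rownames(pair$agent1) <- rownames(pair$agent2) <- NULL
  validate_trajectory_pair(pair)
  pair
}
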