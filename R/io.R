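#' Read a whitespace-separated edge list (SNAP dialect)
#'
#' Two integer columns `src dst` (plus an optional third weight column),
#' one edge per line; lines starting with `#` are comments.  Node ids are
#' used as-is when they already form `0..N-1`, otherwise they are relabeled
#' (the map is kept in `meta$id_map`).
#'
#' @param path file path.
#' @param directed whether the file lists directed edges.
#' @return a `cascade_net`; weights (if present) in `meta$weights`.
#' @export
read_edgelist <- function(path, directed = TRUE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(rows)
  if (any(nf < 2)) {
    bad <- which(keep)[which(nf < 2)[1]]
    stop("edge-list parse error at line ", bad, " of ", path,
         ": expected at least two fields")
  }
  src <- suppressWarnings(as.integer(vapply(rows, `[[`, character(1), 1)))
  dst <- suppressWarnings(as.integer(vapply(rows, `[[`, character(1), 2)))
  if (anyNA(src) || anyNA(dst)) {
    bad <- which(keep)[which(is.na(src) | is.na(dst))[1]]
    stop("edge-list parse error at line ", bad, " of ", path,
         ": non-integer node id")
  }
  w <- if (all(nf >= 3)) as.numeric(vapply(rows, `[[`, character(1), 3)) else NULL
  ids <- sort(unique(c(src, dst)))
  id_map <- NULL
  if (!identical(ids, seq(0L, length(ids) - 1L))) {
    src <- match(src, ids) - 1L
    dst <- match(dst, ids) - 1L
    id_map <- ids
  }
  N <- length(ids)
  el <- cbind(src, dst)
  if (!directed) el <- rbind(el, el[, 2:1, drop = FALSE])
  o <- order(el[, 1], el[, 2])
  offs <- c(0L, cumsum(tabulate(el[o, 1] + 1L, nbins = N)))
  net <- .new_net(N, offs, el[o, 2], directed,
                  meta = list(source = path, id_map = id_map))
  if (!is.null(w)) net$meta$weights <- if (directed) w[o] else c(w, w)[o]
  net
}

#' Write a network as a whitespace-separated edge list
#' @param net a `cascade_net`.
#' @param path output file.
#' @param comment optional comment line(s) written with a `#` prefix.
#' @export
write_edgelist <- function(net, path, comment = NULL) {
  src <- rep.int(seq_len(net$N) - 1L, diff(net$offs))
  el <- cbind(src, net$targ)
  if (!net$directed) el <- el[el[, 1] < el[, 2], , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(paste(el[, 1], el[, 2]), con)
  invisible(path)
}

#' Write / read a probability distribution as a two-column table
#'
#' Plain text with columns `k` and `probability`; offspring, hat and degree
#' distributions all serialize this way.
#'
#' @param x an `offspring_dist`, `qhat_dist`, `degree_dist`, or bare pmf
#'   vector indexed from `k = 0`.
#' @param path output file.
#' @export
write_distribution <- function(x, path) {
  pmf <- if (inherits(x, "offspring_dist")) x$q
         else if (inherits(x, "qhat_dist")) x$qk
         else if (inherits(x, "degree_dist")) x$pmf
         else x
  df <- data.frame(k = seq_along(pmf) - 1, probability = signif(pmf, 9))
  write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_distribution
#' @param what `"offspring"` reads into an empirical `offspring_dist`,
#'   `"degree"` into a `degree_dist`, `"pmf"` returns the bare vector.
#' @export
read_distribution <- function(path, what = c("offspring", "degree", "pmf")) {
  what <- match.arg(what)
  df <- read.table(path, header = TRUE)
  pmf <- numeric(max(df$k) + 1)
  pmf[df$k + 1] <- df$probability
  switch(what,
         pmf = pmf,
         degree = degree_dist(pmf),
         offspring = new_offspring("empirical", list(), q = pmf / sum(pmf),
                                   q_complete = TRUE,
                                   xi = sum((seq_along(pmf) - 1) * pmf) /
                                     sum(pmf),
                                   second_moment_finite = TRUE))
}

#' Build an offspring distribution from a structured-config block
#'
#' The block is a named list `list(family = ..., <params>)`, the same shape
#' written by [write_run_config()].
#' @param cfg named list with `family` and the family parameters.
#' @export
offspring_from_config <- function(cfg) {
  if (is.null(cfg$family)) stop("offspring config is missing the field `family`")
  cfg <- cfg[intersect(names(cfg), names(formals(make_offspring)))]
  do.call(make_offspring, cfg)
}

#' Export a shape curve or estimate as a tab-separated table
#'
#' Columns `t`, `t_over_T`, `value`, `value_rescaled`, `kind`, `T`, with a
#' `#`-prefixed provenance header.
#' @param sc a `shape_curve` or `shape_estimate`.
#' @param path output file.
#' @export
write_shape_table <- function(sc, path) {
  df <- as.data.frame.shape_curve(sc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# avshape shape table v1; kind=", sc$kind,
                    " timescale=", sc$timescale, " T=", sc$T), con)
  suppressWarnings(write.table(format(df, digits = 9), con,
                               row.names = FALSE, quote = FALSE, sep = "\t"))
  invisible(path)
}

#' @rdname write_shape_table
#' @export
read_shape_table <- function(path) {
  df <- read.table(path, header = TRUE, comment.char = "#")
  .new_shape(df$t, df$value, df$T[1], as.character(df$kind[1]), "continuous")
}

#' Serialize an avalanche ensemble as a compact event log
#'
#' Tab-separated rows `avalanche_id`, `t` (bin start or step), `count`,
#' with a provenance header carrying the model, sizes and seed; only
#' nonzero counts are stored.
#' @param ens an `avalanche_ensemble`.
#' @param path output file.
#' @export
write_ensemble_log <- function(ens, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- paste0("# avshape event log v1; model=", ens$model$type,
                " n_A=", ens$n_A, " bin=", ens$bin, " t_cap=", ens$t_cap,
                " timescale=", ens$timescale, " observable=", ens$observable,
                " replica=", ens$replica, " seed=", ens$seed)
  writeLines(c(hdr, "avalanche\tt\tcount"), con)
  step <- if (ens$timescale == "discrete") 1 else ens$bin
  for (a in seq_len(ens$n_A)) {
    p <- ens$profiles[[a]]
    nz <- which(p != 0)
    if (length(nz))
      writeLines(paste(a, (nz - 1) * step, p[nz], sep = "\t"), con)
  }
  writeLines(paste("# durations", paste(signif(ens$durations, 9),
                                        collapse = " ")), con)
  writeLines(paste("# terminated", paste(as.integer(ens$terminated),
                                         collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ensemble_log
#' @export
read_ensemble_log <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  field <- function(name, cast = as.numeric)
    cast(sub(paste0(".*", name, "=([^ ]+).*"), "\\1", hdr))
  durations <- as.numeric(strsplit(sub("^# durations ", "",
                                       grep("^# durations", lines,
                                            value = TRUE)), " ")[[1]])
  terminated <- as.integer(strsplit(sub("^# terminated ", "",
                                        grep("^# terminated", lines,
                                             value = TRUE)), " ")[[1]]) == 1
  body <- lines[!grepl("^#", lines)][-1]
  n_A <- length(durations)
  profiles <- rep(list(integer(0)), n_A)
  bin <- field("bin")
  timescale <- field("timescale", as.character)
  step <- if (timescale == "discrete") 1 else bin
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    a <- as.integer(parts[, 1])
    pos <- as.numeric(parts[, 2]) / step + 1
    cnt <- as.integer(parts[, 3])
    for (g in split(seq_along(a), a)) {
      prof <- integer(max(pos[g]))
      prof[pos[g]] <- cnt[g]
      profiles[[a[g[1]]]] <- prof
    }
  }
  sim <- list(durations = durations, sizes = vapply(profiles, sum, numeric(1)),
              profiles = profiles, terminated = terminated)
  .new_ensemble(sim, list(type = field("model", as.character)), bin,
                field("t_cap"), timescale,
                field("observable", as.character),
                replica = field("replica"), seed = field("seed"))
}

#' Read / write run configurations
#'
#' Run configurations are YAML mappings holding the command, model block,
#' and simulation parameters (`n_A`, `n_R`, `bin`, `t_cap`, `seed`).  Every
#' CLI run writes its resolved configuration next to its outputs.
#' @param path file path.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' @rdname read_run_config
#' @param cfg named list.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
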