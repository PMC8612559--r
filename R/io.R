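#' Write a morphology to SWC
#'
#' One sample per segment (type 1 for the soma, 3 for dendrites, 2 for
#' axonal sections); cylinders are laid out along abstract straight lines,
#' so only topology, radii and path lengths are meaningful.
#'
#' @param morph a \linkS4class{Morphology}
#' @param path output file
#' @return the path, invisibly
#' @export
writeSWC <- function(morph, path) {
  s <- morph@sections
  rows <- list()
  id <- 0
  lastid <- integer(nrow(s))          # last sample id of each section
  names(lastid) <- s$name
  dir <- 0
  for (i in seq_len(nrow(s))) {
    type <- if (s$kind[i] == "sphere") 1L
            else if (grepl("^(axon|ais)", s$name[i])) 2L else 3L
    parent_id <- if (s$parent[i] == "") -1L else lastid[[s$parent[i]]]
    n <- if (s$kind[i] == "sphere") 1L else s$nseg[i]
    # abstract geometry: each section extends radially in its own direction
    dir <- dir + 1
    ang <- dir * 2.399963             # golden angle, keeps lines distinct
    x0 <- 0; y0 <- 0
    if (parent_id > 0) {
      prev <- rows[[parent_id]]
      x0 <- prev$x; y0 <- prev$y
    }
    for (j in seq_len(n)) {
      id <- id + 1
      l <- if (s$kind[i] == "sphere") 0 else s$L[i] / s$nseg[i] * j
      rows[[id]] <- data.frame(
        id = id, type = type,
        x = x0 + l * cos(ang), y = y0 + l * sin(ang), z = 0,
        r = s$diam[i] / 2,
        parent = if (j == 1) parent_id else id - 1L)
    }
    lastid[[s$name[i]]] <- id
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# SWC export; sections: %s",
                     paste(s$name, collapse = " ")), con)
  utils::write.table(format(tab, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SWC morphology
#'
#' Reconstructs a \linkS4class{Morphology} from SWC samples: consecutive
#' same-type samples connected in a chain become one cylindrical section
#' (one segment per sample); the root sample becomes a spherical soma.
#' Cyclic or forward references are rejected.
#'
#' @param path SWC file
#' @return a \linkS4class{Morphology}
#' @export
readSWC <- function(path) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z", "r",
                                         "parent"))
  if (any(tab$parent >= tab$id))
    stop("SWC sample refers to itself or a later sample (cycle)")
  if (sum(tab$parent == -1) != 1) stop("SWC must have exactly one root")
  o <- order(tab$id)
  tab <- tab[o, ]
  root <- which(tab$parent == -1)
  # children count to find branch points
  nchild <- table(factor(tab$parent, levels = tab$id))
  secid <- integer(nrow(tab))
  secid[root] <- 1
  nsec <- 1
  for (i in seq_len(nrow(tab))[-root]) {
    p <- match(tab$parent[i], tab$id)
    newsec <- p == root || nchild[[as.character(tab$id[p])]] > 1 ||
      tab$type[i] != tab$type[p]
    if (newsec) { nsec <- nsec + 1; secid[i] <- nsec }
    else secid[i] <- secid[p]
  }
  secs <- NULL
  for (sid in seq_len(nsec)) {
    idx <- which(secid == sid)
    first <- idx[1]
    if (sid == 1) {
      secs <- .section_row("soma", "sphere", NA_real_, 2 * tab$r[first], 1,
                           naScale = 1, kScale = 1)
      next
    }
    p <- match(tab$parent[first], tab$id)
    parent_name <- if (secid[p] == 1) "soma" else paste0("sec", secid[p])
    seg <- vapply(idx, function(i) {
      pi_ <- match(tab$parent[i], tab$id)
      sqrt((tab$x[i] - tab$x[pi_])^2 + (tab$y[i] - tab$y[pi_])^2 +
           (tab$z[i] - tab$z[pi_])^2)
    }, 1.0)
    secs <- rbind(secs, .section_row(paste0("sec", sid), "cyl",
                                     sum(seg), 2 * stats::median(tab$r[idx]),
                                     length(idx), parent = parent_name))
  }
  new("Morphology", sections = secs, ra = 200, cm = 1.45)
}

#' Write a sweep as CSV
#'
#' Columns: time (ms) and one voltage column (mV) per recording site;
#' recorded synaptic currents (nA), if any, follow as isyn columns.
#'
#' @param sweep a \linkS4class{Sweep}
#' @param path output file
#' @return the path, invisibly
#' @export
writeSweep <- function(sweep, path) {
  tab <- data.frame(time = sweep@time, t(sweep@v))
  names(tab) <- c("time", sweep@sites)
  if (nrow(sweep@isyn) > 0) {
    cur <- t(sweep@isyn)
    colnames(cur) <- paste0("isyn", seq_len(ncol(cur)))
    tab <- cbind(tab, cur)
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a voltage trace from CSV
#'
#' Expects a time column (ms) and at least one voltage column (mV), sampled
#' uniformly. Non-uniform sampling is rejected unless \code{resample} is
#' TRUE, in which case the trace is linearly interpolated to the median dt.
#'
#' @param path CSV file
#' @param resample allow resampling of non-uniform traces
#' @return a \linkS4class{Sweep}
#' @export
readVoltageTrace <- function(path, resample = FALSE) {
  tab <- utils::read.csv(path)
  if (ncol(tab) < 2) stop("expected columns: time, voltage[, ...]")
  t <- tab[[1]]
  if (any(!is.finite(t)) || any(!is.finite(as.matrix(tab[-1]))))
    stop("non-finite values in trace (check file formatting)")
  dts <- diff(t)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(1, dt))) {
    if (!resample)
      stop("non-uniform sampling; pass resample = TRUE to interpolate")
    tt <- seq(min(t), max(t), by = dt)
    tab2 <- data.frame(time = tt)
    for (j in 2:ncol(tab))
      tab2[[names(tab)[j]]] <- stats::approx(t, tab[[j]], xout = tt)$y
    tab <- tab2
    t <- tt
  }
  v <- t(as.matrix(tab[-1]))
  new("Sweep", time = t - t[1], v = v,
      isyn = matrix(numeric(0), nrow = 0, ncol = length(t)),
      dt = dt, sites = names(tab)[-1], diverged = FALSE)
}
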