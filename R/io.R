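## Plain-text I/O: step tables (CSV), work files (single-column CSV) and
## YAML configuration files for pathways, systems and pulling protocols.
## All free energies are kcal/mol with period decimal separator, UTF-8.

#' Read a step-energetics table
#'
#' CSV with at least \code{label, dG_act, dG_rxn} columns (a \code{phase}
#' column and any others are passed through).
#'
#' @param path CSV file path
#' @return data frame
#' @export
read_steps <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("label", "dG_act", "dG_rxn"), names(x))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  x
}

#' Write an annotated step table
#'
#' Derived columns (K, rate constants, lifetimes) are written in
#' scientific notation with 3 significant digits; all other columns are
#' written verbatim.
#'
#' @param x data frame, typically from \code{\link{annotate_steps}}
#' @param path output CSV path
#' @export
write_steps <- function(x, path) {
  y <- as.data.frame(x)
  for (cl in intersect(c("K", "k_f", "k_r", "tau"), names(y)))
    y[[cl]] <- format_sci(y[[cl]])
  utils::write.csv(y, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write work values
#'
#' Single-column CSV of work values in kcal/mol, with header \code{work}
#' (a headerless numeric column is also accepted on read).
#'
#' @param path file path
#' @param T temperature attached to the resulting sample, K
#' @return \code{read_works}: a \code{\link{work_sample}}
#' @export
read_works <- function(path, T = .const$T_default) {
  first <- readLines(path, n = 1)
  if (suppressWarnings(!is.na(as.numeric(first)))) {
    w <- utils::read.csv(path, header = FALSE)[[1]]
  } else {
    x <- utils::read.csv(path)
    if (!"work" %in% names(x)) stop("work file needs a 'work' column")
    w <- x$work
  }
  work_sample(w, T, protocol_id = path)
}

#' @rdname read_works
#' @param sample a \code{work_sample} or numeric vector
#' @export
write_works <- function(sample, path) {
  w <- if (inherits(sample, "work_sample")) sample$works else as.numeric(sample)
  utils::write.csv(data.frame(work = w), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pathway configuration
#'
#' YAML file with an optional \code{temperature} (K) and a \code{processes}
#' list; each process has a \code{name} and a list of \code{steps}, each
#' step a mapping with \code{name}, \code{dG_TS}, \code{dG_step} and
#' optional \code{ts_label} / \code{product_label}.
#'
#' @param path YAML file path
#' @return list with \code{temperature} and \code{processes} (named list of
#'   step data frames, in file order)
#' @export
read_pathway_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$processes) || !length(cfg$processes))
    stop("pathway config must define at least one process")
  procs <- list()
  for (p in cfg$processes) {
    if (is.null(p$name) || is.null(p$steps) || !length(p$steps))
      stop("each process needs a name and a nonempty steps list")
    steps <- do.call(rbind, lapply(p$steps, function(s) {
      data.frame(name = s$name, dG_TS = as.numeric(s$dG_TS),
                 dG_step = as.numeric(s$dG_step),
                 ts_label = if (is.null(s$ts_label)) paste0("TS_", s$name)
                            else s$ts_label,
                 product_label = if (is.null(s$product_label))
                                   paste0("P_", s$name) else s$product_label,
                 stringsAsFactors = FALSE)
    }))
    procs[[p$name]] <- steps
  }
  list(temperature = if (is.null(cfg$temperature)) .const$T_default
                     else as.numeric(cfg$temperature),
       processes = procs)
}

#' Read a toy-system configuration
#'
#' YAML file with \code{atoms} (list of mappings: \code{element},
#' \code{mass}, optional \code{charge}, \code{fixed}, and \code{position}
#' as a 3-vector), optional \code{positions_xyz} (path to an XYZ file,
#' relative to the config, overriding per-atom positions), optional
#' \code{lj_pairs} (list of \code{i, j, A, B}), \code{bonds},
#' \code{angles} and \code{restraints} lists.
#'
#' @param path YAML file path
#' @return a \code{\link{toy_system}}
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$atoms) || !length(cfg$atoms))
    stop("system config must define atoms")
  n <- length(cfg$atoms)
  masses <- vapply(cfg$atoms, function(a) as.numeric(a$mass), numeric(1))
  charges <- vapply(cfg$atoms, function(a)
    if (is.null(a$charge)) 0 else as.numeric(a$charge), numeric(1))
  fixed <- vapply(cfg$atoms, function(a) isTRUE(a$fixed), logical(1))
  if (!is.null(cfg$positions_xyz)) {
    st <- read_xyz(file.path(dirname(path), cfg$positions_xyz))
    if (nrow(st$atoms) != n)
      stop("XYZ atom count does not match the system's atom list")
    pos <- .coords(st)
  } else {
    pos <- t(vapply(cfg$atoms, function(a) as.numeric(a$position), numeric(3)))
  }
  ljA <- matrix(0, n, n); ljB <- matrix(0, n, n)
  for (p in cfg$lj_pairs) {
    i <- p$i; j <- p$j
    ljA[i, j] <- ljA[j, i] <- as.numeric(p$A)
    ljB[i, j] <- ljB[j, i] <- as.numeric(p$B)
  }
  tolist <- function(entries, cols) {
    if (is.null(entries) || !length(entries)) return(NULL)
    do.call(rbind, lapply(entries, function(e)
      as.data.frame(lapply(stats::setNames(cols, cols),
                           function(cl) e[[cl]]))))
  }
  toy_system(masses, pos, charges, ljA, ljB,
             bonds = tolist(cfg$bonds, c("i", "j", "k_b", "r0")),
             angles = tolist(cfg$angles, c("i", "j", "k", "k_theta", "theta0")),
             restraints = tolist(cfg$restraints, c("atom", "axis", "k", "x0")),
             fixed = fixed)
}

#' Read a pulling-protocol configuration
#'
#' YAML file with \code{rc} (\code{"distance i j"} or \code{"diff i j k"}
#' meaning d(i,j) - d(i,k)), \code{lambda_start}, \code{lambda_end},
#' \code{n_steps}, \code{k_spring} and optional \code{dt}, \code{gamma},
#' \code{temperature}, \code{seed}, \code{n_equil}.
#'
#' @param path YAML file path
#' @return a \code{\link{pulling_protocol}}
#' @export
read_protocol_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tok <- strsplit(trimws(as.character(cfg$rc)), "\\s+")[[1]]
  rc <- switch(tok[1],
    distance = reaction_coordinate("distance", as.integer(tok[2:3])),
    diff = reaction_coordinate("distance_difference", as.integer(tok[2:4])),
    stop("rc must start with 'distance' or 'diff'"))
  grab <- function(name, default) {
    if (is.null(cfg[[name]])) default else as.numeric(cfg[[name]])
  }
  pulling_protocol(rc, as.numeric(cfg$lambda_start),
                   as.numeric(cfg$lambda_end), as.integer(cfg$n_steps),
                   as.numeric(cfg$k_spring),
                   dt = grab("dt", 0.5), gamma = grab("gamma", 1),
                   T = grab("temperature", .const$T_default),
                   seed = as.integer(grab("seed", 1)),
                   n_equil = as.integer(grab("n_equil", 0)))
}
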