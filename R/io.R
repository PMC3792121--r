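#' Read and write food-web input tables
#'
#' A food web is exchanged as three delimited UTF-8 text tables (header
#' row, decimal point):
#' \itemize{
#'   \item basic input: `name`, `role`, `B` (t/km2), `PB` (1/yr), `QB`
#'     (1/yr), `EE`, `GS`, `detritus_share`, plus one `landings_<fleet>`
#'     column per fleet (t/km2/yr);
#'   \item diet matrix: `prey` column then one column per predator, diet
#'     fractions (prey rows include `import`);
#'   \item vulnerabilities (optional): `prey` column then one column per
#'     predator, multipliers >= 1.
#' }
#'
#' @param basic,diet Paths to the basic-input and diet tables.
#' @param vulnerabilities Optional path to the vulnerability table.
#' @param delim Field delimiter (default tab).
#' @return `read_foodweb()`: a list with `web` (a [food_web()]) and
#'   `v_table` (tibble `prey`, `predator`, `v`, or NULL).
#' @export
read_foodweb <- function(basic, diet, vulnerabilities = NULL, delim = "\t") {
  gb <- readr::read_delim(basic,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  need <- c("name", "role", "B", "PB", "QB", "EE", "GS")
  miss <- setdiff(need, names(gb))
  if (length(miss) > 0) {
    stop("basic input table is missing column(s): ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  fleet_cols <- grep("^landings_", names(gb), value = TRUE)
  fleets <- sub("^landings_", "", fleet_cols)
  landings <- NULL
  if (length(fleet_cols) > 0) {
    landings <- tidyr::pivot_longer(
      gb[c("name", fleet_cols)], -"name",
      names_to = "fleet", values_to = "landings"
    )
    landings$fleet <- sub("^landings_", "", landings$fleet)
    names(landings)[1] <- "group"
    landings <- landings[!is.na(landings$landings) & landings$landings != 0, ]
  }

  dm <- readr::read_delim(diet,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  if (!"prey" %in% names(dm)) {
    stop("diet table needs a `prey` column", call. = FALSE)
  }
  dlong <- tidyr::pivot_longer(dm, -"prey",
    names_to = "predator", values_to = "proportion"
  )
  dlong <- dlong[!is.na(dlong$proportion) & dlong$proportion != 0, ]

  v_table <- NULL
  if (!is.null(vulnerabilities)) {
    vm <- readr::read_delim(vulnerabilities,
      delim = delim, show_col_types = FALSE, progress = FALSE
    )
    if (!"prey" %in% names(vm)) {
      stop("vulnerability table needs a `prey` column", call. = FALSE)
    }
    v_table <- tidyr::pivot_longer(vm, -"prey",
      names_to = "predator", values_to = "v"
    )
    v_table <- v_table[!is.na(v_table$v), ]
  }

  web <- food_web(
    groups = gb[c(need, intersect("detritus_share", names(gb)))],
    diet = dlong[c("predator", "prey", "proportion")],
    landings = landings,
    fleets = if (length(fleets) > 0) fleets else NULL
  )
  list(web = web, v_table = v_table)
}

#' @rdname read_foodweb
#' @param web A [food_web()].
#' @param dir Output directory (created if needed).
#' @param v_table Optional vulnerability tibble `prey`, `predator`, `v`.
#' @return `write_foodweb()`: the paths of the written tables, invisibly.
#' @export
write_foodweb <- function(web, dir, v_table = NULL, delim = "\t") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- web$groups
  for (f in web$fleets) {
    col <- paste0("landings_", f)
    gb[[col]] <- 0
    rows <- web$landings[web$landings$fleet == f, ]
    gb[[col]][match(rows$group, gb$name)] <- rows$landings
  }
  p_basic <- file.path(dir, "basic_input.tsv")
  readr::write_delim(gb, p_basic, delim = delim)

  D <- diet_matrix(web)
  dm <- tibble::as_tibble(D, rownames = "prey")
  p_diet <- file.path(dir, "diet.tsv")
  readr::write_delim(dm, p_diet, delim = delim)

  p_v <- NULL
  if (!is.null(v_table)) {
    vw <- tidyr::pivot_wider(v_table,
      names_from = "predator", values_from = "v"
    )
    p_v <- file.path(dir, "vulnerabilities.tsv")
    readr::write_delim(vw, p_v, delim = delim)
  }
  invisible(c(basic = p_basic, diet = p_diet, vulnerabilities = p_v))
}

#' Read and write annual forcing series
#'
#' Delimited text with a mandatory `year` column and one column per series
#' (`pp`, `F_<group>`, `cons_<group>`).
#'
#' @param path File path.
#' @param delim Field delimiter.
#' @export
read_forcing <- function(path, delim = "\t") {
  x <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE, progress = FALSE
  )
  if (!"year" %in% names(x)) {
    stop("forcing table needs a `year` column", call. = FALSE)
  }
  x
}

#' @rdname read_forcing
#' @param forcing Forcing tibble.
#' @export
write_forcing <- function(forcing, path, delim = "\t") {
  readr::write_delim(forcing, path, delim = delim)
  invisible(path)
}

#' Export a flow network in SCOR-style text format
#'
#' A plain-text interchange format for compartment flow networks: a title
#' line; a line `n n_living`; `n` compartment lines `index name`; then five
#' blocks — `biomass` (`i value`), `imports` (`i value`), `exports`
#' (`i value`), `respiration` (`i value`) and internal `flows`
#' (`i j value`) — in that order, each terminated by a line containing
#' `-1`.
#'
#' @param net A [flow_network()].
#' @param path Output file.
#' @param title Title line.
#' @return The path, invisibly.
#' @export
write_scor <- function(net, path, title = "flow network") {
  n <- net$n
  living <- net$role != "detritus"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  # compartments ordered living first is not required; keep natural order
  writeLines(paste(n, sum(living)), con)
  writeLines(paste(seq_len(n), net$labels[seq_len(n)]), con)
  blk <- function(lines) writeLines(c(lines, "-1"), con)
  bm <- if (is.null(net$biomass)) rep(0, n) else net$biomass
  blk(sprintf("%d %.10g", seq_len(n), bm))
  imp <- net$T[n + 1L, seq_len(n)]
  blk(sprintf("%d %.10g", which(imp > 0), imp[imp > 0]))
  ex <- net$T[seq_len(n), n + 2L]
  blk(sprintf("%d %.10g", which(ex > 0), ex[ex > 0]))
  re <- net$T[seq_len(n), n + 3L]
  blk(sprintf("%d %.10g", which(re > 0), re[re > 0]))
  idx <- which(net$T[seq_len(n), seq_len(n), drop = FALSE] > 0, arr.ind = TRUE)
  blk(sprintf(
    "%d %d %.10g", idx[, 1], idx[, 2],
    net$T[seq_len(n), seq_len(n)][idx]
  ))
  invisible(path)
}

#' @rdname write_scor
#' @param role Compartment roles (`producer`/`consumer`/`detritus`); the
#'   format itself only records living vs non-living, so roles restore a
#'   read network's detritus flags when provided. Defaults to `consumer`
#'   for living and `detritus` for non-living compartments.
#' @return `read_scor()`: a [flow_network()].
#' @export
read_scor <- function(path, role = NULL) {
  lines <- readLines(path)
  hdr <- scan(text = lines[2], quiet = TRUE)
  n <- as.integer(hdr[1])
  n_living <- as.integer(hdr[2])
  labels <- sub("^\\s*\\d+\\s+", "", lines[3:(2 + n)])
  cur <- 3 + n
  read_block <- function(ncol) {
    out <- list()
    while (trimws(lines[cur]) != "-1") {
      out[[length(out) + 1]] <- scan(text = lines[cur], quiet = TRUE)
      cur <<- cur + 1
    }
    cur <<- cur + 1
    if (length(out) == 0) matrix(numeric(), 0, ncol) else do.call(rbind, out)
  }
  bm <- read_block(2)
  imp <- read_block(2)
  ex <- read_block(2)
  re <- read_block(2)
  fl <- read_block(3)
  labs <- c(labels, "import", "export", "respiration")
  T <- matrix(0, n + 3, n + 3, dimnames = list(labs, labs))
  if (nrow(imp) > 0) T[cbind(n + 1L, as.integer(imp[, 1]))] <- imp[, 2]
  if (nrow(ex) > 0) T[cbind(as.integer(ex[, 1]), n + 2L)] <- ex[, 2]
  if (nrow(re) > 0) T[cbind(as.integer(re[, 1]), n + 3L)] <- re[, 2]
  if (nrow(fl) > 0) {
    T[cbind(as.integer(fl[, 1]), as.integer(fl[, 2]))] <- fl[, 3]
  }
  if (is.null(role)) {
    role <- c(rep("consumer", n_living), rep("detritus", n - n_living))
  }
  biomass <- numeric(n)
  if (nrow(bm) > 0) biomass[as.integer(bm[, 1])] <- bm[, 2]
  flow_network(
    T = T, labels = labs, role = role, biomass = biomass,
    quiet = TRUE
  )
}

#' Write an indicator (or any year-indexed) table
#'
#' Delimited text with a first comment line naming the units.
#'
#' @param data Year-indexed tibble.
#' @param path Output file.
#' @param units Unit comment written as a `#` header line.
#' @param delim Field delimiter.
#' @export
write_indicators <- function(data, path,
                             units = "# flows t/km2/yr; information bits; indices dimensionless",
                             delim = "\t") {
  con <- file(path, "w")
  writeLines(units, con)
  close(con)
  readr::write_delim(data, path, delim = delim, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_indicators
#' @export
read_indicators <- function(path, delim = "\t") {
  readr::read_delim(path,
    delim = delim, comment = "#", show_col_types = FALSE, progress = FALSE
  )
}
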