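#' @keywords internal
"_PACKAGE"

# Internal units everywhere: millilitres, millilitres/hour, hours, pg/ml.
# Config files and helpers accept microlitres and convert on the boundary.

MODULE_ROLES <- c("donor", "acceptor", "tissue", "blank")
FLOW_KINDS <- c("through", "recirculation")
BALANCE_TOL <- 1e-9 # ml/h

#' Convert microlitres to millilitres
#'
#' Flow hardware is specified in microlitres and microlitres per hour; the
#' model works in millilitres and millilitres per hour so that a steady
#' concentration is production/flow in pg/ml without unit factors.
#'
#' @param x numeric, microlitres (or microlitres/hour).
#' @return millilitres (or millilitres/hour).
#' @export
ul_to_ml <- function(x) x / 1000

#' Convert millilitres to microlitres
#' @param x numeric, millilitres (or millilitres/hour).
#' @return microlitres (or microlitres/hour).
#' @export
ml_to_ul <- function(x) x * 1000

#' Convert a mass concentration to a molar concentration
#'
#' pg/ml equals ng/l, so dividing by the molar mass in g/mol gives nmol/l.
#'
#' @param pg_per_ml mass concentration in pg/ml.
#' @param molar_mass molar mass of the analyte in g/mol
#'   (e.g. 272.38 for oestradiol, 314.46 for progesterone).
#' @return concentration in nmol/l.
#' @export
pg_per_ml_to_nmol_per_l <- function(pg_per_ml, molar_mass) {
  stopifnot(molar_mass > 0)
  pg_per_ml / molar_mass
}

#' @rdname pg_per_ml_to_nmol_per_l
#' @param nmol_per_l molar concentration in nmol/l.
#' @export
nmol_per_l_to_pg_per_ml <- function(nmol_per_l, molar_mass) {
  stopifnot(molar_mass > 0)
  nmol_per_l * molar_mass
}

#' Construct a culture-module description
#'
#' A module is one well-mixed compartment of a platform: a donor (fresh-media
#' reservoir), acceptor (spent-media collection and sampling module), a
#' tissue module, or a blank spare.
#'
#' @param id short unique identifier.
#' @param role one of `"donor"`, `"acceptor"`, `"tissue"`, `"blank"`.
#' @param volume_ml media volume in millilitres (> 0).
#' @param tissue_label optional label (`"follicle"`, `"fallopian"`,
#'   `"uterus"`, `"ectocervix"`, `"liver"`).
#' @return a one-row data frame with columns `id`, `role`, `tissue_label`,
#'   `volume_ml`.
#' @export
mfp_module <- function(id, role, volume_ml, tissue_label = NA_character_) {
  role <- match.arg(role, MODULE_ROLES)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("module 'id' must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L || !is.finite(volume_ml) ||
      volume_ml <= 0) {
    stop("module '", id, "' must have volume_ml > 0", call. = FALSE)
  }
  data.frame(id = id, role = role, tissue_label = as.character(tissue_label),
             volume_ml = volume_ml, stringsAsFactors = FALSE)
}

#' Construct a directed flow path between two modules
#'
#' @param src,dst module ids (must differ).
#' @param rate_ml_h flow rate in ml/h (>= 0).
#' @param kind `"through"` (donor-to-acceptor direction) or
#'   `"recirculation"` (loop flow returning media upstream).
#' @param redundancy number of independent pump pathways serving this
#'   segment (>= 1); platforms carry two for fail-safe rerouting.
#' @return a one-row data frame with columns `src`, `dst`, `rate_ml_h`,
#'   `kind`, `redundancy`.
#' @export
mfp_path <- function(src, dst, rate_ml_h, kind = "through", redundancy = 2L) {
  kind <- match.arg(kind, FLOW_KINDS)
  if (identical(src, dst)) stop("flow path src and dst must differ", call. = FALSE)
  if (!is.numeric(rate_ml_h) || rate_ml_h < 0 || !is.finite(rate_ml_h)) {
    stop("flow path rate must be a finite nonnegative ml/h value", call. = FALSE)
  }
  if (redundancy < 1) stop("redundancy must be >= 1", call. = FALSE)
  data.frame(src = src, dst = dst, rate_ml_h = rate_ml_h, kind = kind,
             redundancy = as.integer(redundancy), stringsAsFactors = FALSE)
}

#' Assemble and validate a platform configuration
#'
#' @param name platform name.
#' @param modules data frame of modules (rows from [mfp_module()]).
#' @param paths data frame of flow paths (rows from [mfp_path()]); may be
#'   empty.
#' @param preset optional preset tag recorded for rebuilds during design
#'   search.
#' @return an object of class `platform_config` with fields `name`,
#'   `modules`, `paths`, `donor_id`, `acceptor_id`.
#' @export
platform_config <- function(name, modules, paths, preset = NULL) {
  stopifnot(is.data.frame(modules), is.data.frame(paths))
  if (anyDuplicated(modules$id)) {
    stop("module ids must be unique within a platform", call. = FALSE)
  }
  if (any(modules$volume_ml <= 0)) {
    stop("all module volumes must be positive", call. = FALSE)
  }
  donor_id <- modules$id[modules$role == "donor"]
  acceptor_id <- modules$id[modules$role == "acceptor"]
  if (length(donor_id) != 1L || length(acceptor_id) != 1L) {
    stop("a platform needs exactly one donor and one acceptor module",
         call. = FALSE)
  }
  if (nrow(paths) > 0) {
    unknown <- setdiff(unique(c(paths$src, paths$dst)), modules$id)
    if (length(unknown)) {
      stop("flow path references unknown module(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(paths$rate_ml_h < 0)) stop("flow rates must be >= 0", call. = FALSE)
    if (any(paths$src == paths$dst)) stop("paths must join distinct modules",
                                          call. = FALSE)
  }
  structure(
    list(name = name, modules = modules, paths = paths,
         donor_id = donor_id, acceptor_id = acceptor_id, preset = preset),
    class = "platform_config")
}

#' @export
print.platform_config <- function(x, ...) {
  cat("<platform_config> ", x$name, "\n", sep = "")
  cat("  modules: ", nrow(x$modules), " (donor=", x$donor_id,
      ", acceptor=", x$acceptor_id, ")\n", sep = "")
  wired <- x$paths[x$paths$rate_ml_h > 0, , drop = FALSE]
  cat("  paths:   ", nrow(x$paths), " (", nrow(wired), " carrying flow)\n",
      sep = "")
  invisible(x)
}

QUINTET_TISSUES <- c("follicle", "fallopian", "uterus", "ectocervix", "liver")

#' Build a preset platform configuration
#'
#' Three presets mirror the laboratory platforms:
#' \describe{
#'   \item{solo}{donor, one tissue module, acceptor; through-flow
#'     0.040 ml/h.}
#'   \item{duet}{donor, two tissue modules in series, acceptor;
#'     through-flow 0.040 ml/h.}
#'   \item{quintet}{twelve modules: donor, five tissue modules
#'     (follicle, fallopian, uterus, ectocervix, liver), acceptor and five
#'     unwired blank spares; through-flow 0.100 ml/h plus a recirculation
#'     loop returning media from the ectocervix module to the follicle
#'     module. Through segments inside the loop carry `Q_D + Q_R` so every
#'     intermediate module is flow-balanced.}
#' }
#' All culture modules default to 0.700 ml of media.
#'
#' @param preset `"solo"`, `"duet"` or `"quintet"`.
#' @param overrides optional named list; `overrides$volume` is a named
#'   vector of per-module volumes in ml keyed by module id.
#' @param through_flow through-system flow rate Q_D in ml/h (preset default
#'   if `NULL`).
#' @param recirc_flow recirculating flow rate Q_R in ml/h (quintet only;
#'   defaults to Q_D).
#' @param tissue_volume single volume in ml applied to all tissue modules.
#' @return a flow-balanced [platform_config()].
#' @examples
#' q <- make_platform("quintet")
#' nrow(q$modules) # 12
#' validate_flow_balance(q) # empty: balanced by construction
#' @export
make_platform <- function(preset = c("solo", "duet", "quintet"),
                          overrides = NULL, through_flow = NULL,
                          recirc_flow = NULL, tissue_volume = NULL) {
  preset <- match.arg(preset)
  v <- if (is.null(tissue_volume)) 0.700 else tissue_volume
  if (v <= 0) stop("tissue_volume must be positive", call. = FALSE)

  if (preset == "solo") {
    q <- if (is.null(through_flow)) 0.040 else through_flow
    if (q < 0) stop("through_flow must be >= 0", call. = FALSE)
    modules <- rbind(
      mfp_module("donor", "donor", 0.700),
      mfp_module("tissue", "tissue", v, "follicle"),
      mfp_module("acceptor", "acceptor", 0.700))
    paths <- rbind(
      mfp_path("donor", "tissue", q),
      mfp_path("tissue", "acceptor", q))
  } else if (preset == "duet") {
    q <- if (is.null(through_flow)) 0.040 else through_flow
    if (q < 0) stop("through_flow must be >= 0", call. = FALSE)
    modules <- rbind(
      mfp_module("donor", "donor", 0.700),
      mfp_module("tissue1", "tissue", v, "follicle"),
      mfp_module("tissue2", "tissue", v, "fallopian"),
      mfp_module("acceptor", "acceptor", 0.700))
    paths <- rbind(
      mfp_path("donor", "tissue1", q),
      mfp_path("tissue1", "tissue2", q),
      mfp_path("tissue2", "acceptor", q))
  } else {
    q <- if (is.null(through_flow)) 0.100 else through_flow
    qr <- if (is.null(recirc_flow)) q else recirc_flow
    if (q < 0 || qr < 0) stop("flow rates must be >= 0", call. = FALSE)
    modules <- rbind(
      mfp_module("donor", "donor", 0.700),
      do.call(rbind, lapply(QUINTET_TISSUES, function(lab) {
        mfp_module(lab, "tissue", v, lab)
      })),
      mfp_module("acceptor", "acceptor", 0.700),
      do.call(rbind, lapply(1:5, function(i) {
        mfp_module(paste0("blank", i), "blank", 0.700)
      })))
    # blanks are spare capacity and stay unwired (zero flow)
    paths <- rbind(
      mfp_path("donor", "follicle", q),
      mfp_path("follicle", "fallopian", q + qr),
      mfp_path("fallopian", "uterus", q + qr),
      mfp_path("uterus", "ectocervix", q + qr),
      mfp_path("ectocervix", "liver", q),
      mfp_path("ectocervix", "follicle", qr, kind = "recirculation"),
      mfp_path("liver", "acceptor", q))
  }

  if (!is.null(overrides)) {
    if (!is.list(overrides)) stop("overrides must be a list", call. = FALSE)
    vol <- overrides$volume
    if (!is.null(vol)) {
      unknown <- setdiff(names(vol), modules$id)
      if (length(unknown)) {
        stop("volume override references unknown module(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      if (any(vol <= 0)) {
        stop("volume override must leave all volumes positive", call. = FALSE)
      }
      modules$volume_ml[match(names(vol), modules$id)] <- as.numeric(vol)
    }
  }

  cfg <- platform_config(paste0(preset, "-MFP"), modules, paths,
                         preset = preset)
  bal <- validate_flow_balance(cfg)
  stopifnot(nrow(bal) == 0L)
  cfg
}

#' Check steady incompressible flow balance
#'
#' At steady operation every module that is neither the donor (a source)
#' nor the acceptor (a sink) must receive exactly as much flow as it emits.
#' Recirculation paths count like any other flow, so a loop entering and
#' leaving a module at equal rates is balance-neutral.
#'
#' @param config a [platform_config()].
#' @param tol imbalance tolerance in ml/h.
#' @return a data frame of violations with columns `module_id` and
#'   `imbalance_ml_h` (inflow minus outflow); zero rows when balanced.
#' @export
validate_flow_balance <- function(config, tol = BALANCE_TOL) {
  stopifnot(inherits(config, "platform_config"))
  ids <- config$modules$id
  inflow <- outflow <- stats::setNames(numeric(length(ids)), ids)
  p <- config$paths
  if (nrow(p) > 0) {
    for (i in seq_len(nrow(p))) {
      outflow[p$src[i]] <- outflow[p$src[i]] + p$rate_ml_h[i]
      inflow[p$dst[i]] <- inflow[p$dst[i]] + p$rate_ml_h[i]
    }
  }
  net <- inflow - outflow
  bad <- character(0); imb <- numeric(0)
  for (id in ids) {
    role <- config$modules$role[config$modules$id == id]
    viol <- switch(role,
      donor = net[id] > tol,          # source: must not be a net receiver
      acceptor = -net[id] > tol,      # sink: must not be a net emitter
      abs(net[id]) > tol)
    if (isTRUE(viol)) { bad <- c(bad, id); imb <- c(imb, net[id]) }
  }
  data.frame(module_id = bad, imbalance_ml_h = imb, stringsAsFactors = FALSE)
}

#' Order modules along the through-flow direction
#'
#' Topologically sorts the modules touched by `kind = "through"` paths from
#' donor to acceptor; recirculation paths are ignored. Unwired blanks are
#' excluded.
#'
#' @param config a flow-balanced [platform_config()].
#' @return character vector of module ids from donor to acceptor.
#' @export
transit_order <- function(config) {
  stopifnot(inherits(config, "platform_config"))
  p <- config$paths[config$paths$kind == "through", , drop = FALSE]
  nodes <- unique(c(config$donor_id, p$src, p$dst))
  nodes <- config$modules$id[config$modules$id %in% nodes] # stable order
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(p))) indeg[p$dst[i]] <- indeg[p$dst[i]] + 1L
  order_out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) {
      stop("cycle detected among through-flow paths", call. = FALSE)
    }
    nxt <- ready[1L]
    order_out <- c(order_out, nxt)
    remaining <- setdiff(remaining, nxt)
    out_edges <- p[p$src == nxt, , drop = FALSE]
    for (d in out_edges$dst) indeg[d] <- indeg[d] - 1L
  }
  order_out
}

#' Read a platform configuration from a structured text file
#'
#' The file is YAML with a `modules:` block (fields `id`, `role`,
#' `volume_ul`) and a `paths:` block (fields `src`, `dst`, `rate_ul_per_h`,
#' `kind`, `redundancy`). Volumes and rates are in microlitres and are
#' converted to the package's internal millilitre units.
#'
#' @param path file path.
#' @return a [platform_config()].
#' @export
read_platform_config <- function(path) {
  doc <- yaml::read_yaml(path)
  for (block in c("modules", "paths")) {
    if (is.null(doc[[block]])) {
      stop("platform config file '", path, "' is missing the '", block,
           "' block", call. = FALSE)
    }
  }
  modules <- do.call(rbind, lapply(doc$modules, function(m) {
    mfp_module(m$id, m$role, ul_to_ml(m$volume_ul),
               if (is.null(m$tissue_label)) NA_character_ else m$tissue_label)
  }))
  paths <- do.call(rbind, lapply(doc$paths, function(p) {
    mfp_path(p$src, p$dst, ul_to_ml(p$rate_ul_per_h),
             kind = if (is.null(p$kind)) "through" else p$kind,
             redundancy = if (is.null(p$redundancy)) 2L else p$redundancy)
  }))
  if (is.null(paths)) {
    paths <- mfp_path("a", "b", 0)[0, ]
  }
  platform_config(if (is.null(doc$name)) basename(path) else doc$name,
                  modules, paths)
}

#' Write a platform configuration to a structured text file
#'
#' Inverse of [read_platform_config()]; values are written in microlitres.
#'
#' @param config a [platform_config()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_platform_config <- function(config, path) {
  stopifnot(inherits(config, "platform_config"))
  doc <- list(
    name = config$name,
    modules = lapply(seq_len(nrow(config$modules)), function(i) {
      m <- config$modules[i, ]
      out <- list(id = m$id, role = m$role, volume_ul = ml_to_ul(m$volume_ml))
      if (!is.na(m$tissue_label)) out$tissue_label <- m$tissue_label
      out
    }),
    paths = lapply(seq_len(nrow(config$paths)), function(i) {
      p <- config$paths[i, ]
      list(src = p$src, dst = p$dst, rate_ul_per_h = ml_to_ul(p$rate_ml_h),
           kind = p$kind, redundancy = p$redundancy)
    }))
  writeLines(c("# schema_version: 1", yaml::as.yaml(doc)), path)
  invisible(path)
}
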