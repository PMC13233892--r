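## Configuration, presets, output writers and the command-line entry point.

#' Load and validate a study configuration
#'
#' Configurations are YAML files with a `study` kind (`mms`, `squeeze`,
#' `pvs` or `pvs-sweep`), a `params` block of material constants and
#' study-specific blocks. Two presets ship with the package:
#' `"table1"` (verification/benchmark constants) and `"table2"`
#' (perivascular peristalsis constants). All values are SI.
#'
#' @param path Path to a YAML file, or the name of a packaged preset.
#' @return A validated `study_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    preset <- system.file("presets", paste0(path, ".yaml"),
                          package = "porozero")
    if (nzchar(preset)) path <- preset
    else stop("config file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$params)) stop("config is missing required block 'params'")
  req <- c("rho_s_true", "rho_f_true", "mu_f", "kappa_bar", "phi_fc", "mu_s")
  miss <- setdiff(req, names(cfg$params))
  if (length(miss)) stop("config params block is missing key(s): ",
                         paste(miss, collapse = ", "))
  cfg$material <- do.call(material_params, cfg$params[req])
  if (!is.null(cfg$peristalsis)) {
    pz <- cfg$peristalsis
    for (k in c("lambda", "f", "h", "R_o", "b"))
      if (is.null(pz[[k]])) stop("peristalsis block missing key: ", k)
    phiR <- if (!is.null(pz$porosity_profile)) {
      pp <- pz$porosity_profile
      referential_porosity(type = "profile", phi_f0 = pp$phi_f0,
                           phi_f_inf = pp$phi_f_inf, h = pz$h,
                           R_bar = pp$R_bar)
    } else referential_porosity(pz$phi_Rf %||% 0.2)
    cfg$peristalsis_config <- peristalsis_config(
      lambda = pz$lambda, f = pz$f, h = pz$h, R_o = pz$R_o, b = pz$b,
      Dp = pz$Dp %||% 0, params = cfg$material, phiR = phiR,
      n_r = pz$n_r %||% 50L, n_z = pz$n_z %||% 96L,
      grade_r = pz$grade_r %||% 1)
  }
  structure(cfg, class = "study_config")
}

#' Write study outputs to disk
#'
#' Writes tables as CSV, reports and metadata as JSON, and fields as ASCII
#' VTU (VTK unstructured grid) files, with deterministic names inside
#' `dir`.
#'
#' @param outputs Named list; elements of class `convergence_report` or
#'   data frames are written as JSON/CSV, lists as JSON, and elements of
#'   the form `list(mesh =, fields =)` as VTU.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(outputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(outputs)) {
    x <- outputs[[nm]]
    if (inherits(x, "convergence_report")) {
      p1 <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(list(case = x$case, errors = x$errors,
                                rates = as.list(x$rates),
                                rates_tail = as.list(x$rates_tail),
                                dt = x$dt, T_final = x$T_final),
                           p1, auto_unbox = TRUE, digits = NA)
      p2 <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x$errors, p2, row.names = FALSE)
      paths <- c(paths, p1, p2)
    } else if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(x, p, row.names = FALSE)
      paths <- c(paths, p)
    } else if (is.list(x) && !is.null(x$mesh) && !is.null(x$fields)) {
      p <- file.path(dir, paste0(nm, ".vtu"))
      write_vtu(x$mesh, x$fields, p)
      paths <- c(paths, p)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Write an unstructured-grid VTU file
#'
#' Minimal ASCII VTK XML writer for triangle meshes with nodal scalar or
#' two-component vector fields (padded to 3D as VTK expects).
#'
#' @param mesh An `axisym_mesh`.
#' @param fields Named list of nodal fields: numeric vectors (scalars) or
#'   two-column matrices (r, z components).
#' @param file Output path.
#' @export
write_vtu <- function(mesh, fields, file) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m)
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], 0), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(paste(mesh$tri[, 1] - 1L, mesh$tri[, 2] - 1L, mesh$tri[, 3] - 1L),
             con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(paste(3L * seq_len(m)), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(rep("5", m), con)
  w('        </DataArray>')
  w('      </Cells>')
  w('      <PointData>')
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (is.matrix(f)) {
      w('        <DataArray type="Float64" Name="%s" NumberOfComponents="3" format="ascii">', nm)
      writeLines(paste(f[, 1], f[, 2], 0), con)
    } else {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(paste(f), con)
    }
    w('        </DataArray>')
  }
  w('      </PointData>')
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
  invisible(file)
}

#' Command-line entry point
#'
#' Subcommands: `mms-verify` (convergence study; `--case phi05|phi0`),
#' `squeeze` (locally compressed cylinder benchmark), `pvs` (one
#' peristalsis case), `pvs-sweep` (`--axis domain-length|outer-radius`,
#' `--values` comma-separated, in meters). Common options: `--preset` /
#' `--config`, `--out` (output directory), and scale overrides
#' (`--levels`, `--nz`, `--nr`, `--dt`, `--tfinal`).
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- function() {
    cat("usage: porozero <mms-verify|squeeze|pvs|pvs-sweep> [options]\n",
        "  --preset NAME | --config FILE   parameter source (default table1/table2)\n",
        "  --out DIR                       output directory (default '.')\n",
        "  --case phi05|phi0               mms case\n",
        "  --levels N --dt X --tfinal X    study scale\n",
        "  --nr N --nz N                   peristalsis mesh\n",
        "  --axis A --values v1,v2,...     sweep axis and values (m)\n")
  }
  if (!length(argv)) { usage(); return(1L) }
  cmd <- argv[1]
  opts <- list(out = ".")
  i <- 2L
  while (i <= length(argv)) {
    k <- sub("^--", "", argv[i])
    if (i + 1L > length(argv)) { usage(); return(1L) }
    opts[[k]] <- argv[i + 1L]
    i <- i + 2L
  }
  num <- function(k, d) if (is.null(opts[[k]])) d else as.numeric(opts[[k]])
  cfg_name <- opts$config %||% opts$preset %||%
    (if (cmd %in% c("pvs", "pvs-sweep")) "table2" else "table1")
  cfg <- tryCatch(load_config(cfg_name), error = function(e) e)
  if (inherits(cfg, "error")) { message(conditionMessage(cfg)); return(1L) }
  ok <- tryCatch({
    if (cmd == "mms-verify") {
      rep <- run_convergence_study(opts$case %||% "phi05",
                                   levels = as.integer(num("levels", 4)),
                                   dt = num("dt", 5e-4),
                                   T_final = num("tfinal", 5e-2),
                                   params = cfg$material, quiet = FALSE)
      print(rep)
      write_outputs(list(convergence_report = rep), opts$out)
    } else if (cmd == "squeeze") {
      sq <- squeeze_config(params = cfg$material,
                           h_e = num("he", 1e-4), dt = num("dt", 1e-3),
                           T_final = num("tfinal", 2))
      run <- run_squeeze_benchmark(sq, quiet = FALSE)
      names(run$probe)[1:3] <- c("t_s", "phi_point", "phi_line_avg")
      write_outputs(list(porosity_probe = run$probe[1:3],
                         squeeze_summary = list(
                           converged = run$converged,
                           min_phi = min(run$probe$min_phi))), opts$out)
      if (!run$converged) message("run stopped early at t = ", run$failure$t)
    } else if (cmd == "pvs") {
      pc <- cfg$peristalsis_config
      if (!is.null(opts$nr)) pc$n_r <- as.integer(num("nr", pc$n_r))
      if (!is.null(opts$nz)) pc$n_z <- as.integer(num("nz", pc$n_z))
      res <- run_peristalsis_case(pc, quiet = FALSE)
      print(res)
      write_outputs(list(pvs_summary = res$summary,
                         pvs_fields = list(mesh = res$ctx$mesh, fields =
                           peristalsis_nodal_fields(res))), opts$out)
    } else if (cmd == "pvs-sweep") {
      pc <- cfg$peristalsis_config
      if (!is.null(opts$nr)) pc$n_r <- as.integer(num("nr", pc$n_r))
      if (!is.null(opts$nz)) pc$n_z <- as.integer(num("nz", pc$n_z))
      vals <- as.numeric(strsplit(opts$values %||% "", ",")[[1]])
      if (!length(vals)) stop("pvs-sweep requires --values")
      tab <- run_parameter_sweep(opts$axis %||% "domain-length", vals, pc,
                                 quiet = FALSE)
      print(tab)
      write_outputs(list(sweep = tab), opts$out)
    } else { usage(); return(1L) }
    TRUE
  }, error = function(e) { message("error: ", conditionMessage(e)); FALSE })
  if (ok) 0L else 1L
}

## nodal diagnostic fields of a peristalsis result (for VTU export)
peristalsis_nodal_fields <- function(res) {
  ctx <- res$ctx; lay <- ctx$layout; nd <- ctx$mesh$nodes
  pts <- cbind(pmin(pmax(nd[, 1], min(nd[, 1]) + 1e-12),
                    max(nd[, 1]) - 1e-12), nd[, 2])
  f <- eval_state_fields(res$U, ctx, pts)
  list(u_s = f$u, v_f = f$v_f, p = f$p, phi_f = f$phi_f, J = f$J)
}
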