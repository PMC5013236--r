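# internal helpers shared across modules

.trim <- function(x) trimws(x, which = "both")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All stochastic code in the package funnels through this; no global seeding.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    seed <- as.integer(seed)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

# INFO-level log line; silenced with options(netarch.verbose = FALSE)
.log <- function(...) {
    if (isTRUE(getOption("netarch.verbose", TRUE))) {
        message("INFO [netarch] ", ...)
    }
}

.checkClean <- function(net, fun) {
    if (!isClean(net)) {
        stop(fun, "() requires a clean network (no self-loops, no duplicate ",
             "edges); run cleanNetwork() first", call. = FALSE)
    }
    invisible(TRUE)
}
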