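# Internal layer wrappers around the C++ kernels. Weight arrays follow the
# R layout (kh, kw, cin, cout); the C++ side consumes them flattened
# column-major, which matches matrix(w, kh*kw*cin, cout).

conv_fwd <- function(x, w, b, pad) {
  dw <- dim(w)
  cpp_conv2d_fwd(x, matrix(w, dw[1] * dw[2] * dw[3], dw[4]), b,
                 dw[1], dw[2], as.integer(pad))
}

conv_bwd <- function(x, w, gout, pad) {
  dw <- dim(w)
  g <- cpp_conv2d_bwd(x, matrix(w, dw[1] * dw[2] * dw[3], dw[4]), gout,
                      dw[1], dw[2], as.integer(pad))
  list(gx = g$gx, gw = array(g$gw, dw), gb = as.numeric(g$gb))
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bwd <- function(pre, gout) {
  gout * (pre > 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (!all(da[1:2] == db[1:2])) {
    stop("cannot concatenate feature maps with different spatial dims",
         call. = FALSE)
  }
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

split_channels <- function(x, n_first) {
  d <- dim(x)
  list(array(x[, , seq_len(n_first)], c(d[1], d[2], n_first)),
       array(x[, , (n_first + 1):d[3]], c(d[1], d[2], d[3] - n_first)))
}

# double 3x3 conv + ReLU block
dconv_fwd <- function(x, p, prefix) {
  z1 <- conv_fwd(x, p[[paste0(prefix, ".c1.w")]], p[[paste0(prefix, ".c1.b")]], 1L)
  a1 <- relu_fwd(z1)
  z2 <- conv_fwd(a1, p[[paste0(prefix, ".c2.w")]], p[[paste0(prefix, ".c2.b")]], 1L)
  a2 <- relu_fwd(z2)
  list(out = a2, x = x, z1 = z1, a1 = a1, z2 = z2)
}

dconv_bwd <- function(cache, p, prefix, gout, grads) {
  g2 <- relu_bwd(cache$z2, gout)
  c2 <- conv_bwd(cache$a1, p[[paste0(prefix, ".c2.w")]], g2, 1L)
  grads[[paste0(prefix, ".c2.w")]] <- c2$gw
  grads[[paste0(prefix, ".c2.b")]] <- c2$gb
  g1 <- relu_bwd(cache$z1, c2$gx)
  c1 <- conv_bwd(cache$x, p[[paste0(prefix, ".c1.w")]], g1, 1L)
  grads[[paste0(prefix, ".c1.w")]] <- c1$gw
  grads[[paste0(prefix, ".c1.b")]] <- c1$gb
  grads[["..gx"]] <- c1$gx
  grads
}
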