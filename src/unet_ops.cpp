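// Low-level layer kernels for the U-net: zero-padded k x k convolution
// (im2col + BLAS GEMM), 2x2 max pooling, and 2x2 stride-2 up-convolution
// (transposed convolution).  Feature maps are H x W x C arma::cubes;
// convolution weights are (Cout) x (Cin*k*k) matrices with row-within-block
// order (channel, kernel col, kernel row); up-convolution weights are
// (4*Cout) x (Cin) with the four 2x2 taps stacked as dd = di + 2*dj.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;
using Rcpp::List;

static mat im2col_pad(const cube& x, int k) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices, p = (k - 1) / 2;
    mat out(C * k * k, H * W, fill::zeros);
    for (int c = 0; c < C; ++c)
        for (int dj = -p; dj <= p; ++dj)
            for (int di = -p; di <= p; ++di) {
                const int r = c * k * k + (dj + p) * k + (di + p);
                for (int j = 0; j < W; ++j) {
                    const int js = j + dj;
                    if (js < 0 || js >= W) continue;
                    for (int i = 0; i < H; ++i) {
                        const int is = i + di;
                        if (is < 0 || is >= H) continue;
                        out(r, i + H * j) = x(is, js, c);
                    }
                }
            }
    return out;
}

static cube col2im_pad(const mat& cols, int H, int W, int C, int k) {
    const int p = (k - 1) / 2;
    cube x(H, W, C, fill::zeros);
    for (int c = 0; c < C; ++c)
        for (int dj = -p; dj <= p; ++dj)
            for (int di = -p; di <= p; ++di) {
                const int r = c * k * k + (dj + p) * k + (di + p);
                for (int j = 0; j < W; ++j) {
                    const int js = j + dj;
                    if (js < 0 || js >= W) continue;
                    for (int i = 0; i < H; ++i) {
                        const int is = i + di;
                        if (is < 0 || is >= H) continue;
                        x(is, js, c) += cols(r, i + H * j);
                    }
                }
            }
    return x;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& Wt,
                        const arma::vec& b, int k) {
    const int H = x.n_rows, W = x.n_cols;
    const int Cout = Wt.n_rows;
    mat Y = Wt * im2col_pad(x, k);
    Y.each_col() += b;
    cube y(H, W, Cout);
    for (int co = 0; co < Cout; ++co)
        y.slice(co) = reshape(Y.row(co).t(), H, W);
    return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& Wt,
                  const arma::cube& dy, int k) {
    const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
    const int Cout = dy.n_slices;
    mat dY(Cout, H * W);
    for (int co = 0; co < Cout; ++co)
        dY.row(co) = vectorise(dy.slice(co)).t();
    mat cols = im2col_pad(x, k);
    mat dW = dY * cols.t();
    vec db = sum(dY, 1);
    cube dx = col2im_pad(Wt.t() * dY, H, W, Cin, k);
    return List::create(Rcpp::Named("dx") = dx,
                        Rcpp::Named("dW") = dW,
                        Rcpp::Named("db") = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int Ho = H / 2, Wo = W / 2;
    cube y(Ho, Wo, C);
    Rcpp::IntegerVector idx(Ho * Wo * C);
    int t = 0;
    for (int c = 0; c < C; ++c)
        for (int j = 0; j < Wo; ++j)
            for (int i = 0; i < Ho; ++i) {
                double best = -datum::inf;
                int besti = 0;
                for (int dj = 0; dj < 2; ++dj)
                    for (int di = 0; di < 2; ++di) {
                        const int ii = 2 * i + di, jj = 2 * j + dj;
                        const double v = x(ii, jj, c);
                        if (v > best) {
                            best = v;
                            besti = ii + H * jj + H * W * c;
                        }
                    }
                y(i, j, c) = best;
                idx[t++] = besti;
            }
    return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const Rcpp::IntegerVector& idx,
                           const arma::cube& dy, int H, int W) {
    const int C = dy.n_slices;
    cube dx(H, W, C, fill::zeros);
    const int Ho = dy.n_rows, Wo = dy.n_cols;
    int t = 0;
    for (int c = 0; c < C; ++c)
        for (int j = 0; j < Wo; ++j)
            for (int i = 0; i < Ho; ++i)
                dx(idx[t++]) += dy(i, j, c);
    return dx;
}

// [[Rcpp::export]]
arma::cube cpp_upconv_fwd(const arma::cube& x, const arma::mat& Wt,
                          const arma::vec& b) {
    const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
    const int Cout = Wt.n_rows / 4;
    mat X(Cin, H * W);
    for (int c = 0; c < Cin; ++c)
        X.row(c) = vectorise(x.slice(c)).t();
    cube y(2 * H, 2 * W, Cout);
    for (int dd = 0; dd < 4; ++dd) {
        const int di = dd % 2, dj = dd / 2;
        mat Y = Wt.rows(dd * Cout, (dd + 1) * Cout - 1) * X;  // Cout x HW
        Y.each_col() += b;
        for (int co = 0; co < Cout; ++co)
            for (int j = 0; j < W; ++j)
                for (int i = 0; i < H; ++i)
                    y(2 * i + di, 2 * j + dj, co) = Y(co, i + H * j);
    }
    return y;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(const arma::cube& x, const arma::mat& Wt,
                    const arma::cube& dy) {
    const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
    const int Cout = dy.n_slices;
    mat X(Cin, H * W);
    for (int c = 0; c < Cin; ++c)
        X.row(c) = vectorise(x.slice(c)).t();
    mat dW(4 * Cout, Cin, fill::zeros);
    vec db(Cout, fill::zeros);
    mat dX(Cin, H * W, fill::zeros);
    mat dY(Cout, H * W);
    for (int dd = 0; dd < 4; ++dd) {
        const int di = dd % 2, dj = dd / 2;
        for (int co = 0; co < Cout; ++co)
            for (int j = 0; j < W; ++j)
                for (int i = 0; i < H; ++i)
                    dY(co, i + H * j) = dy(2 * i + di, 2 * j + dj, co);
        dW.rows(dd * Cout, (dd + 1) * Cout - 1) = dY * X.t();
        db += sum(dY, 1);
        dX += Wt.rows(dd * Cout, (dd + 1) * Cout - 1).t() * dY;
    }
    cube dx(H, W, Cin);
    for (int c = 0; c < Cin; ++c)
        dx.slice(c) = reshape(dX.row(c).t(), H, W);
    return List::create(Rcpp::Named("dx") = dx,
                        Rcpp::Named("dW") = dW,
                        Rcpp::Named("db") = db);
}
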