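#include <Rcpp.h>
#include <deque>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact 1-D fused-lasso / total-variation denoising:
//   minimise  sum_i (y_i - x_i)^2 + lambda * sum_i |x_{i+1} - x_i|
// by dynamic programming over clipped piecewise-quadratic value functions
// (Johnson-style message passing). The derivative of the running value
// function f_i is piecewise linear and non-decreasing; the inf-convolution
// with lambda*|.| clips it to [-lambda, +lambda]. Each data term adds the
// linear derivative 2x - 2 y_i uniformly, tracked lazily via (A, B).
//
// Pieces store the *stored* derivative a*x + b on [left, next.left); the true
// derivative is (a + A)*x + (b + B).

struct Piece {
    double left;
    double a;
    double b;
};

// [[Rcpp::export(name = ".tv1d_cpp")]]
NumericVector tv1d_cpp(NumericVector y, double lambda) {
    const int n = y.size();
    NumericVector x(n);
    if (n == 0) return x;
    if (n == 1 || lambda <= 0.0) {
        for (int i = 0; i < n; ++i) x[i] = y[i];
        return x;
    }

    const double NEG_INF = -std::numeric_limits<double>::infinity();
    std::deque<Piece> pieces;
    double A = 2.0, B = -2.0 * y[0];           // f_1'(x) = 2x - 2 y_1
    pieces.push_back({NEG_INF, 0.0, 0.0});

    std::vector<double> lo(n), hi(n);

    for (int i = 1; i < n; ++i) {
        // clip the left tail at derivative = -lambda
        while (pieces.size() > 1) {
            const Piece &p = pieces.front();
            double xr = pieces[1].left;
            double dr = (p.a + A) * xr + (p.b + B);
            if (dr < -lambda) pieces.pop_front(); else break;
        }
        {
            Piece &p = pieces.front();
            double slope = p.a + A;
            double bminus;
            if (slope > 1e-12) {
                bminus = (-lambda - (p.b + B)) / slope;
                if (pieces.size() > 1 && bminus > pieces[1].left)
                    bminus = pieces[1].left;
            } else {
                // flat front piece already at >= -lambda: clip at its left
                bminus = p.left;
            }
            lo[i] = bminus;
            p.left = bminus;
            pieces.push_front({NEG_INF, -A, -lambda - B});
        }

        // clip the right tail at derivative = +lambda
        while (pieces.size() > 1) {
            const Piece &p = pieces.back();
            double xl = p.left;
            double dl = (p.a + A) * xl + (p.b + B);
            if (dl > lambda) pieces.pop_back(); else break;
        }
        {
            Piece &p = pieces.back();
            double slope = p.a + A;
            double bplus;
            if (slope > 1e-12) {
                bplus = (lambda - (p.b + B)) / slope;
                if (bplus < p.left) bplus = p.left;
            } else {
                bplus = p.left;
            }
            hi[i] = bplus;
            pieces.push_back({bplus, -A, lambda - B});
        }

        // add the data term (y_i - x)^2
        A += 2.0;
        B += -2.0 * y[i];
    }

    // minimise f_n: find the zero crossing of the true derivative
    double xstar = 0.0;
    {
        size_t j = 0;
        for (; j + 1 < pieces.size(); ++j) {
            const Piece &p = pieces[j];
            double xr = pieces[j + 1].left;
            double dr = (p.a + A) * xr + (p.b + B);
            if (dr >= 0.0) break;
        }
        const Piece &p = pieces[j];
        double slope = p.a + A;
        if (slope > 1e-12) {
            xstar = (0.0 - (p.b + B)) / slope;
            if (p.left > NEG_INF && xstar < p.left) xstar = p.left;
        } else {
            xstar = p.left;
        }
    }

    x[n - 1] = xstar;
    for (int i = n - 1; i >= 1; --i) {
        double v = x[i];
        if (v < lo[i]) v = lo[i];
        if (v > hi[i]) v = hi[i];
        x[i - 1] = v;
    }
    return x;
}
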