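// Minimal convolutional-network engine for pileup-segment regression:
// 3x3 same-padding convolutions + ReLU, max pooling, dense layers, sigmoid
// head, MSE loss, Glorot-uniform init, Adam. Single-threaded and fully
// deterministic given the seed (own RNG; no std distribution objects, whose
// output is implementation-defined).
#include <RcppArmadillo.h>
#include <cstdint>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rng {
    uint64_t s;
    explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
    uint64_t next() { // splitmix64
        uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        return z ^ (z >> 31);
    }
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
    int below(int n) { return (int)(next() % (uint64_t)n); }
};

enum LType { CONV, POOL, DENSE };

struct Layer {
    LType type;
    int cout = 0;          // conv filters
    int ph = 1, pw = 1;    // pool window
    int units = 0;         // dense units
    // shapes
    int inD = 0, inL = 0, inC = 0;
    int outD = 0, outL = 0, outC = 0;
    int inFlat = 0;        // dense input size
    bool finalLayer = false;
};

std::vector<Layer> parseArch(List arch, int D, int L, int C) {
    std::vector<Layer> layers;
    int d = D, l = L, c = C;
    bool seenDense = false;
    int flat = 0;
    for (int i = 0; i < arch.size(); ++i) {
        List spec = arch[i];
        std::string type = as<std::string>(spec["type"]);
        Layer lay;
        if (type == "conv") {
            if (seenDense) stop("conv layer after dense layer");
            lay.type = CONV;
            lay.cout = as<int>(spec["filters"]);
            lay.inD = d; lay.inL = l; lay.inC = c;
            lay.outD = d; lay.outL = l; lay.outC = lay.cout;
            c = lay.cout;
        } else if (type == "pool") {
            if (seenDense) stop("pool layer after dense layer");
            lay.type = POOL;
            lay.ph = as<int>(spec["ph"]);
            lay.pw = as<int>(spec["pw"]);
            lay.inD = d; lay.inL = l; lay.inC = c;
            lay.outD = d / lay.ph; lay.outL = l / lay.pw; lay.outC = c;
            if (lay.outD < 1 || lay.outL < 1)
                stop("pooling collapses a spatial axis below 1 (input %dx%d, pool %dx%d)",
                     d, l, lay.ph, lay.pw);
            d = lay.outD; l = lay.outL;
        } else if (type == "dense") {
            lay.type = DENSE;
            lay.units = as<int>(spec["units"]);
            lay.inFlat = seenDense ? flat : d * l * c;
            flat = lay.units;
            seenDense = true;
        } else {
            stop("unknown layer type '%s'", type.c_str());
        }
        layers.push_back(lay);
    }
    if (layers.empty() || layers.back().type != DENSE || layers.back().units != 1)
        stop("architecture must end with a single-unit dense layer");
    for (size_t i = 0; i < layers.size(); ++i)
        layers[i].finalLayer = (i == layers.size() - 1);
    return layers;
}

// im2col for 3x3, pad 1: out (9*Cin) x (D*L), patch order (dr,dc) outer,
// channel inner
void im2col3(const arma::cube &x, arma::mat &cols) {
    const int D = x.n_rows, L = x.n_cols, C = x.n_slices;
    cols.zeros(9 * C, D * L);
    for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
            const int pidx = (dr + 1) + 3 * (dc + 1);
            for (int ch = 0; ch < C; ++ch) {
                const int rowi = pidx * C + ch;
                for (int cc = 0; cc < L; ++cc) {
                    const int sc = cc + dc;
                    if (sc < 0 || sc >= L) continue;
                    for (int rr = 0; rr < D; ++rr) {
                        const int sr = rr + dr;
                        if (sr < 0 || sr >= D) continue;
                        cols(rowi, rr + D * cc) = x(sr, sc, ch);
                    }
                }
            }
        }
    }
}

void col2im3(const arma::mat &dcols, arma::cube &dx, int D, int L, int C) {
    dx.zeros(D, L, C);
    for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
            const int pidx = (dr + 1) + 3 * (dc + 1);
            for (int ch = 0; ch < C; ++ch) {
                const int rowi = pidx * C + ch;
                for (int cc = 0; cc < L; ++cc) {
                    const int sc = cc + dc;
                    if (sc < 0 || sc >= L) continue;
                    for (int rr = 0; rr < D; ++rr) {
                        const int sr = rr + dr;
                        if (sr < 0 || sr >= D) continue;
                        dx(sr, sc, ch) += dcols(rowi, rr + D * cc);
                    }
                }
            }
        }
    }
}

struct Params {
    std::vector<arma::mat> W;
    std::vector<arma::vec> b;
    std::vector<int> layerOf; // index into layers
};

Params unpackWeights(const std::vector<Layer> &layers, List weights) {
    Params p;
    int wi = 0;
    for (size_t i = 0; i < layers.size(); ++i) {
        if (layers[i].type == POOL) continue;
        if (wi >= weights.size()) stop("weight list too short for architecture");
        List lw = weights[wi++];
        p.W.push_back(as<arma::mat>(lw["W"]));
        p.b.push_back(as<arma::vec>(lw["b"]));
        p.layerOf.push_back((int)i);
        const Layer &lay = layers[i];
        if (lay.type == CONV) {
            if ((int)p.W.back().n_rows != lay.cout ||
                (int)p.W.back().n_cols != 9 * lay.inC)
                stop("conv weight shape mismatch at layer %d", (int)i + 1);
        } else {
            if ((int)p.W.back().n_rows != lay.units ||
                (int)p.W.back().n_cols != lay.inFlat)
                stop("dense weight shape mismatch at layer %d", (int)i + 1);
        }
    }
    if (wi != weights.size()) stop("weight list longer than architecture");
    return p;
}

struct Tape { // per-sample forward activations
    std::vector<arma::cube> cubeOut;   // post-activation output per cube layer
    std::vector<arma::mat> convCols;   // im2col inputs per conv
    std::vector<arma::ucube> poolArg;  // argmax offsets (encoded) per pool
    std::vector<arma::vec> denseOut;   // post-activation per dense
    arma::vec flatIn;                  // flattened cube entering first dense
};

double forwardOne(const std::vector<Layer> &layers, const Params &p,
                  const double *xmem, int D, int L, int C, Tape *tape) {
    arma::cube cur(const_cast<double *>(xmem), D, L, C);
    arma::cube cube = cur; // copy
    arma::vec vecAct;
    bool inDense = false;
    int pi = 0; // param index
    Tape localTape;
    Tape &tp = tape ? *tape : localTape;
    for (size_t i = 0; i < layers.size(); ++i) {
        const Layer &lay = layers[i];
        if (lay.type == CONV) {
            arma::mat cols;
            im2col3(cube, cols);
            arma::mat out = p.W[pi] * cols;
            out.each_col() += p.b[pi];
            arma::cube next(lay.outD, lay.outL, lay.outC);
            for (int ch = 0; ch < lay.outC; ++ch) {
                arma::rowvec r = out.row(ch);
                next.slice(ch) = arma::reshape(r, lay.outD, lay.outL);
            }
            next.transform([](double v) { return v > 0 ? v : 0.0; }); // ReLU
            if (tape) { tp.convCols.push_back(std::move(cols)); }
            cube = std::move(next);
            if (tape) tp.cubeOut.push_back(cube);
            ++pi;
        } else if (lay.type == POOL) {
            arma::cube next(lay.outD, lay.outL, lay.outC);
            arma::ucube argm(lay.outD, lay.outL, lay.outC);
            for (int ch = 0; ch < lay.outC; ++ch) {
                for (int oc = 0; oc < lay.outL; ++oc) {
                    for (int orr = 0; orr < lay.outD; ++orr) {
                        double best = -1e300; unsigned bi = 0;
                        for (int dc = 0; dc < lay.pw; ++dc) {
                            for (int dr = 0; dr < lay.ph; ++dr) {
                                const int rr = orr * lay.ph + dr, cc = oc * lay.pw + dc;
                                const double v = cube(rr, cc, ch);
                                if (v > best) { best = v; bi = rr + lay.inD * cc; }
                            }
                        }
                        next(orr, oc, ch) = best;
                        argm(orr, oc, ch) = bi;
                    }
                }
            }
            cube = std::move(next);
            if (tape) { tp.poolArg.push_back(std::move(argm)); tp.cubeOut.push_back(cube); }
        } else { // DENSE
            arma::vec in;
            if (!inDense) {
                in = arma::vectorise(cube);
                if (tape) tp.flatIn = in;
                inDense = true;
            } else {
                in = vecAct;
            }
            arma::vec out = p.W[pi] * in + p.b[pi];
            if (lay.finalLayer) {
                out[0] = 1.0 / (1.0 + std::exp(-out[0])); // sigmoid head
            } else {
                out.transform([](double v) { return v > 0 ? v : 0.0; });
            }
            vecAct = std::move(out);
            if (tape) tp.denseOut.push_back(vecAct);
            ++pi;
        }
    }
    return vecAct[0];
}

// backward for one sample; accumulates into gW/gb; dLoss/dPred supplied
void backwardOne(const std::vector<Layer> &layers, const Params &p,
                 const Tape &tp, const double *xmem, int D, int L, int C,
                 double dpred, std::vector<arma::mat> &gW,
                 std::vector<arma::vec> &gb) {
    const int nP = (int)p.W.size();
    // walk layers backwards
    int pi = nP - 1;
    int di = (int)tp.denseOut.size() - 1;   // dense activation index
    int ci = (int)tp.cubeOut.size() - 1;    // cube activation index
    int convi = (int)tp.convCols.size() - 1;
    int pooli = (int)tp.poolArg.size() - 1;
    arma::vec dvec;  // gradient wrt current dense activation
    arma::cube dcube;
    bool inDense = true;
    for (int i = (int)layers.size() - 1; i >= 0; --i) {
        const Layer &lay = layers[i];
        if (lay.type == DENSE) {
            const arma::vec &out = tp.denseOut[di];
            arma::vec dz;
            if (lay.finalLayer) {
                const double s = out[0];
                dz = arma::vec(1);
                dz[0] = dpred * s * (1.0 - s);
            } else {
                dz = dvec;
                for (arma::uword j = 0; j < dz.n_elem; ++j)
                    if (out[j] <= 0) dz[j] = 0;
            }
            const bool firstDense = (i == 0) || (layers[i - 1].type != DENSE);
            const arma::vec &in = firstDense ? tp.flatIn : tp.denseOut[di - 1];
            gW[pi] += dz * in.t();
            gb[pi] += dz;
            arma::vec din = p.W[pi].t() * dz;
            if (firstDense) {
                // reshape into cube gradient
                const Layer *prevCube = nullptr;
                for (int j = i - 1; j >= 0; --j)
                    if (layers[j].type != DENSE) { prevCube = &layers[j]; break; }
                if (prevCube) {
                    dcube = arma::cube(din.memptr(), prevCube->outD, prevCube->outL,
                                       prevCube->outC);
                } else {
                    dcube = arma::cube(din.memptr(), D, L, C);
                }
                inDense = false;
            } else {
                dvec = std::move(din);
            }
            --di; --pi;
        } else if (lay.type == POOL) {
            const arma::ucube &argm = tp.poolArg[pooli];
            arma::cube dx(lay.inD, lay.inL, lay.inC, arma::fill::zeros);
            for (int ch = 0; ch < lay.outC; ++ch)
                for (int oc = 0; oc < lay.outL; ++oc)
                    for (int orr = 0; orr < lay.outD; ++orr) {
                        const unsigned bi = argm(orr, oc, ch);
                        dx(bi % lay.inD, bi / lay.inD, ch) += dcube(orr, oc, ch);
                    }
            dcube = std::move(dx);
            --pooli; --ci;
        } else { // CONV
            // ReLU gate on this layer's output
            const arma::cube &act = tp.cubeOut[ci];
            for (arma::uword j = 0; j < dcube.n_elem; ++j)
                if (act[j] <= 0) dcube[j] = 0;
            // assemble dOut matrix (Cout x D*L)
            arma::mat dout(lay.outC, lay.outD * lay.outL);
            for (int ch = 0; ch < lay.outC; ++ch) {
                arma::mat sl = dcube.slice(ch);
                dout.row(ch) = arma::vectorise(sl).t();
            }
            gW[pi] += dout * tp.convCols[convi].t();
            gb[pi] += arma::sum(dout, 1);
            if (i > 0) { // gradient into previous cube
                arma::mat dcols = p.W[pi].t() * dout;
                arma::cube dx;
                col2im3(dcols, dx, lay.inD, lay.inL, lay.inC);
                dcube = std::move(dx);
            }
            --convi; --ci; --pi;
        }
    }
    (void)inDense;
}

} // namespace

// [[Rcpp::export]]
List cnn_init_cpp(List arch, int D, int L, int C, int seed) {
    std::vector<Layer> layers = parseArch(arch, D, L, C);
    Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
    List out;
    for (size_t i = 0; i < layers.size(); ++i) {
        const Layer &lay = layers[i];
        if (lay.type == POOL) continue;
        int nr, nc;
        double fanIn, fanOut;
        if (lay.type == CONV) {
            nr = lay.cout; nc = 9 * lay.inC;
            fanIn = 9.0 * lay.inC; fanOut = 9.0 * lay.cout;
        } else {
            nr = lay.units; nc = lay.inFlat;
            fanIn = lay.inFlat; fanOut = lay.units;
        }
        const double limit = std::sqrt(6.0 / (fanIn + fanOut)); // Glorot uniform
        NumericMatrix W(nr, nc);
        for (int j = 0; j < nr * nc; ++j) W[j] = (2.0 * rng.unif() - 1.0) * limit;
        NumericVector b(nr); // zeros
        out.push_back(List::create(_["W"] = W, _["b"] = b));
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(List arch, List weights, NumericMatrix X,
                              int D, int L, int C) {
    std::vector<Layer> layers = parseArch(arch, D, L, C);
    Params p = unpackWeights(layers, weights);
    const int N = X.nrow();
    if (X.ncol() != D * L * C)
        stop("input has %d values per sample; architecture expects %d (%d x %d x %d)",
             X.ncol(), D * L * C, D, L, C);
    NumericVector out(N);
    std::vector<double> buf(D * L * C);
    for (int i = 0; i < N; ++i) {
        for (int j = 0; j < D * L * C; ++j) buf[j] = X(i, j);
        out[i] = forwardOne(layers, p, buf.data(), D, L, C, nullptr);
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return out;
}

// [[Rcpp::export]]
List cnn_train_cpp(List arch, List weights, NumericMatrix X, NumericVector y,
                   int D, int L, int C, int epochs, int batchSize, double lr,
                   int seed) {
    std::vector<Layer> layers = parseArch(arch, D, L, C);
    Params p = unpackWeights(layers, weights);
    const int N = X.nrow();
    if (N == 0) stop("empty training set");
    if (X.ncol() != D * L * C)
        stop("input has %d values per sample; architecture expects %d (%d x %d x %d)",
             X.ncol(), D * L * C, D, L, C);
    const int nP = (int)p.W.size();
    std::vector<arma::mat> mW(nP), vW(nP), gW(nP);
    std::vector<arma::vec> mb(nP), vb(nP), gb(nP);
    for (int i = 0; i < nP; ++i) {
        mW[i].zeros(arma::size(p.W[i])); vW[i].zeros(arma::size(p.W[i]));
        gW[i].zeros(arma::size(p.W[i]));
        mb[i].zeros(p.b[i].n_elem); vb[i].zeros(p.b[i].n_elem);
        gb[i].zeros(p.b[i].n_elem);
    }
    const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
    long t = 0;
    Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 17ULL);
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    NumericVector history(epochs);
    std::vector<double> buf(D * L * C);
    Tape tape;
    for (int ep = 0; ep < epochs; ++ep) {
        // Fisher-Yates shuffle
        for (int i = N - 1; i > 0; --i) {
            int j = rng.below(i + 1);
            std::swap(idx[i], idx[j]);
        }
        double lossSum = 0;
        int done = 0;
        while (done < N) {
            const int bs = std::min(batchSize, N - done);
            for (int i = 0; i < nP; ++i) { gW[i].zeros(); gb[i].zeros(); }
            for (int s = 0; s < bs; ++s) {
                const int r = idx[done + s];
                for (int j = 0; j < D * L * C; ++j) buf[j] = X(r, j);
                tape = Tape();
                const double pred = forwardOne(layers, p, buf.data(), D, L, C, &tape);
                const double err = pred - y[r];
                lossSum += err * err;
                backwardOne(layers, p, tape, buf.data(), D, L, C, 2.0 * err / bs,
                            gW, gb);
            }
            ++t;
            const double bc1 = 1.0 - std::pow(beta1, (double)t);
            const double bc2 = 1.0 - std::pow(beta2, (double)t);
            for (int i = 0; i < nP; ++i) {
                mW[i] = beta1 * mW[i] + (1 - beta1) * gW[i];
                vW[i] = beta2 * vW[i] + (1 - beta2) * arma::square(gW[i]);
                p.W[i] -= lr * (mW[i] / bc1) / (arma::sqrt(vW[i] / bc2) + eps);
                mb[i] = beta1 * mb[i] + (1 - beta1) * gb[i];
                vb[i] = beta2 * vb[i] + (1 - beta2) * arma::square(gb[i]);
                p.b[i] -= lr * (mb[i] / bc1) / (arma::sqrt(vb[i] / bc2) + eps);
            }
            done += bs;
            Rcpp::checkUserInterrupt();
        }
        history[ep] = lossSum / N;
    }
    List wOut;
    for (int i = 0; i < nP; ++i)
        wOut.push_back(List::create(_["W"] = wrap(p.W[i]), _["b"] = wrap(p.b[i])));
    return List::create(_["weights"] = wOut, _["history"] = history);
}
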