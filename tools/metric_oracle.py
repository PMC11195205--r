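#!/usr/bin/env python
"""Independent reference metrics (numpy/scipy/scikit-image).

Reads two matrices from CSV files, prints PSNR, SSIM and MS-SSIM. Used to
compute the frozen expected values asserted by the R test suite; the MS-SSIM
here is implemented directly from the standard multi-scale definition
(Gaussian 11x1.5 window, valid positions only, 2x2 area pooling between
levels, luminance term at the coarsest level, weights renormalized for the
level count) and shares no code with the R implementation.
"""
import sys
import numpy as np
from scipy.signal import convolve2d
from skimage.metrics import structural_similarity, peak_signal_noise_ratio


def gauss_win(size=11, sigma=1.5):
    r = np.arange(size) - (size - 1) / 2
    w = np.exp(-r**2 / (2 * sigma**2))
    return w / w.sum()


def valid_filter(m, w):
    k = np.outer(w, w)
    return convolve2d(m, k[::-1, ::-1], mode="valid")


def ssim_cs(x, y, data_range=1.0):
    C1 = (0.01 * data_range) ** 2
    C2 = (0.03 * data_range) ** 2
    w = gauss_win()
    mx = valid_filter(x, w)
    my = valid_filter(y, w)
    sxx = valid_filter(x * x, w) - mx**2
    syy = valid_filter(y * y, w) - my**2
    sxy = valid_filter(x * y, w) - mx * my
    l = (2 * mx * my + C1) / (mx**2 + my**2 + C1)
    cs = (2 * sxy + C2) / (sxx + syy + C2)
    return l, cs


def avgpool2(m):
    h, w = (m.shape[0] // 2) * 2, (m.shape[1] // 2) * 2
    m = m[:h, :w]
    return m.reshape(h // 2, 2, w // 2, 2).mean(axis=(1, 3))


def ms_ssim(x, y, levels, data_range=1.0, eps=1e-6):
    w5 = np.array([0.0448, 0.2856, 0.3001, 0.2363, 0.1333])[:levels]
    w5 = w5 / w5.sum()
    vals = []
    for j in range(levels):
        l, cs = ssim_cs(x, y, data_range)
        vals.append(cs.mean() if j < levels - 1 else (l * cs).mean())
        if j < levels - 1:
            x, y = avgpool2(x), avgpool2(y)
    vals = np.maximum(np.array(vals), eps)
    return float(np.prod(vals ** w5))


def main():
    a = np.loadtxt(sys.argv[1], delimiter=",")
    b = np.loadtxt(sys.argv[2], delimiter=",")
    levels = int(sys.argv[3]) if len(sys.argv) > 3 else 3
    ps = peak_signal_noise_ratio(a, b, data_range=1.0)
    ss = structural_similarity(a, b, gaussian_weights=True, sigma=1.5,
                               use_sample_covariance=False, data_range=1.0)
    ms = ms_ssim(a, b, levels)
    print(f"{ps:.10f} {ss:.10f} {ms:.10f}")


if __name__ == "__main__":
    main()
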