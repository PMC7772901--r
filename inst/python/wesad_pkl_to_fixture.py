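#!/usr/bin/env python
"""Convert one native per-subject pickle record to the wearnet plain-text
columnar fixture format.

Usage: wesad_pkl_to_fixture.py <subject.pkl> <out.txt>

Expected pickle layout (as distributed): a dict with keys
  'subject' -> id string (optional; falls back to the file stem)
  'signal'  -> {'chest': {...}, 'wrist': {...}} of numpy arrays
  'label'   -> integer condition codes at 700 Hz
Chest channels all 700 Hz; wrist BVP 64 Hz, ACC 32 Hz, EDA/TEMP 4 Hz.
Three-axis ACC arrays may be nested (N x 3) or flat (3N); both are split
into ACC_X/ACC_Y/ACC_Z.
"""
import pickle
import sys
from pathlib import Path

import numpy as np

CHEST_RATE = 700
WRIST_RATES = {"BVP": 64, "ACC": 32, "EDA": 4, "TEMP": 4}
# name normalisation: dataset key -> package channel identifier
NAME_MAP = {"ECG": "ECG", "EDA": "EDA", "EMG": "EMG", "RESP": "RESP",
            "TEMP": "TEMP", "ACC": "ACC", "BVP": "BVP"}


def die(msg):
    sys.stderr.write(msg + "\n")
    sys.exit(1)


def norm_key(k):
    return NAME_MAP.get(str(k).upper(), None)


def split_acc(arr):
    a = np.asarray(arr, dtype=float)
    if a.ndim == 2 and a.shape[1] == 3:
        return a[:, 0], a[:, 1], a[:, 2]
    if a.ndim == 2 and a.shape[0] == 3:
        return a[0], a[1], a[2]
    a = a.ravel()
    if a.size % 3:
        die("schema error: ACC array length %d is not divisible by 3" % a.size)
    n = a.size // 3
    return a[:n], a[n:2 * n], a[2 * n:]


def main():
    if len(sys.argv) != 3:
        die(__doc__)
    src, dst = Path(sys.argv[1]), Path(sys.argv[2])
    try:
        with open(src, "rb") as fh:
            data = pickle.load(fh, encoding="latin1")
    except OSError as e:
        die("I/O error: %s" % e)
    except Exception as e:  # noqa: BLE001 - report any unpickling failure
        die("schema error: cannot unpickle '%s': %s" % (src, e))

    if "signal" not in data or "label" not in data:
        die("schema error: record lacks 'signal'/'label' keys")
    subject = str(data.get("subject", src.stem))
    labels = np.asarray(data["label"], dtype=float).ravel()

    cols = []  # (site, name, rate, values)
    for site, rates in (("chest", None), ("wrist", WRIST_RATES)):
        sig = data["signal"].get(site)
        if sig is None:
            die("schema error: missing '%s' signal group" % site)
        found = {}
        for key, arr in sig.items():
            nk = norm_key(key)
            if nk is None:
                continue
            found[nk] = arr
        expected = ["ECG", "EDA", "EMG", "RESP", "TEMP", "ACC"] \
            if site == "chest" else ["BVP", "ACC", "EDA", "TEMP"]
        for name in expected:
            if name not in found:
                die("schema error: missing %s channel '%s'" % (site, name))
            rate = CHEST_RATE if site == "chest" else rates[name]
            if name == "ACC":
                for ax, v in zip("XYZ", split_acc(found[name])):
                    cols.append((site, "ACC_" + ax, rate, v))
            else:
                cols.append((site, name, rate,
                             np.asarray(found[name], dtype=float).ravel()))
    cols.append(("label", "labels", CHEST_RATE, labels))

    nmax = max(len(v) for _, _, _, v in cols)
    with open(dst, "w") as out:
        out.write("# wearnet subject fixture v1\n")
        out.write("# subject: %s\n" % subject)
        for site, name, rate, v in cols:
            out.write("# channel: %s %s %g %d\n" % (site, name, rate, len(v)))
        body = np.full((nmax, len(cols)), "NA", dtype=object)
        for j, (site, name, rate, v) in enumerate(cols):
            fmt = "%d" if site == "label" else "%.17g"
            body[: len(v), j] = [fmt % x for x in v]
        out.write("\n".join("\t".join(row) for row in body))
        out.write("\n")


if __name__ == "__main__":
    main()
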