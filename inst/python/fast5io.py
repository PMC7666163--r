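#!/usr/bin/env python
"""Bulk fast5 (HDF5) <-> per-channel CSV bridge.

Layout handled: /Raw/Channel_<id>/Signal datasets, sampling rate on the
channel's Meta group (attribute 'sample_rate' or 'sampling_rate'). Integer
DAC signals are converted to pA when calibration attributes (range,
digitisation, offset) are present.

Usage:
    fast5io.py dump <file.fast5> <outdir> [channel ...]
    fast5io.py pack <file.fast5> <indir>

dump writes <outdir>/channel_<id>.csv (one value per line) and
<outdir>/meta.tsv (columns: channel, sampling_rate, n).
pack reads the same layout and builds the fast5 file.
"""
import os
import sys

import h5py
import numpy as np


def die(msg):
    sys.stderr.write("fast5io: " + msg + "\n")
    sys.exit(1)


def channel_attrs(group):
    attrs = dict(group.attrs)
    if "Meta" in group:
        attrs.update(dict(group["Meta"].attrs))
    return attrs


def dump(path, outdir, channels):
    with h5py.File(path, "r") as f:
        if "Raw" not in f:
            die("format error: no raw channel datasets in " + path)
        avail = {}
        for name in f["Raw"]:
            if name.startswith("Channel_"):
                try:
                    avail[int(name.split("_", 1)[1])] = name
                except ValueError:
                    continue
        if not avail:
            die("format error: no Channel_* groups under /Raw in " + path)
        if channels is None:
            channels = sorted(avail)
        rows = []
        for ch in channels:
            if ch not in avail:
                die("lookup error: unknown channel id %d" % ch)
            g = f["Raw"][avail[ch]]
            if "Signal" not in g:
                die("format error: channel %d has no Signal dataset" % ch)
            sig = np.asarray(g["Signal"][...])
            attrs = channel_attrs(g)
            if np.issubdtype(sig.dtype, np.integer) and all(
                k in attrs for k in ("range", "digitisation", "offset")
            ):
                sig = (sig.astype(np.float64) + float(attrs["offset"])) * (
                    float(attrs["range"]) / float(attrs["digitisation"])
                )
            rate = float(attrs.get("sample_rate",
                                   attrs.get("sampling_rate", 3012.0)))
            np.savetxt(os.path.join(outdir, "channel_%d.csv" % ch),
                       np.asarray(sig, dtype=np.float64), fmt="%.17g")
            rows.append((ch, rate, len(sig)))
        with open(os.path.join(outdir, "meta.tsv"), "w") as fh:
            fh.write("channel\tsampling_rate\tn\n")
            for ch, rate, n in rows:
                fh.write("%d\t%.17g\t%d\n" % (ch, rate, n))


def pack(path, indir):
    meta_path = os.path.join(indir, "meta.tsv")
    if not os.path.exists(meta_path):
        die("pack: missing meta.tsv in " + indir)
    rows = []
    with open(meta_path) as fh:
        header = fh.readline()
        for line in fh:
            parts = line.rstrip("\n").split("\t")
            rows.append((int(parts[0]), float(parts[1])))
    with h5py.File(path, "w") as f:
        raw = f.create_group("Raw")
        for ch, rate in rows:
            sig = np.loadtxt(os.path.join(indir, "channel_%d.csv" % ch),
                             dtype=np.float64, ndmin=1)
            g = raw.create_group("Channel_%d" % ch)
            g.create_dataset("Signal", data=sig)
            meta = g.create_group("Meta")
            meta.attrs["sample_rate"] = rate


def main(argv):
    if len(argv) < 3:
        die("usage: fast5io.py dump|pack <file.fast5> <dir> [channels...]")
    cmd, path, d = argv[0], argv[1], argv[2]
    if cmd == "dump":
        if not os.path.exists(path):
            die("I/O error: no such file: " + path)
        channels = [int(c) for c in argv[3:]] or None
        dump(path, d, channels)
    elif cmd == "pack":
        pack(path, d)
    else:
        die("unknown command: " + cmd)


if __name__ == "__main__":
    main(sys.argv[1:])
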