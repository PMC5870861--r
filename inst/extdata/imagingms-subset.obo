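format-version: 1.2
data-version: 1.1.0-subset
ontology: ims
remark: Reduced test subset of the imagingMS controlled vocabulary covering the term subtrees used by the default imzML extraction ruleset. Not the full vocabulary.

[Term]
id: IMS:1000003
name: ibd binary type

[Term]
id: IMS:1000030
name: continuous
is_a: IMS:1000003 ! ibd binary type

[Term]
id: IMS:1000031
name: processed
is_a: IMS:1000003 ! ibd binary type

[Term]
id: IMS:1000080
name: universally unique identifier

[Term]
id: IMS:1000009
name: ibd checksum

[Term]
id: IMS:1000090
name: ibd MD5
is_a: IMS:1000009 ! ibd checksum

[Term]
id: IMS:1000091
name: ibd SHA-1
is_a: IMS:1000009 ! ibd checksum

[Term]
id: IMS:1000040
name: scan direction

[Term]
id: IMS:1000401
name: top down
is_a: IMS:1000040 ! scan direction

[Term]
id: IMS:1000402
name: bottom up
is_a: IMS:1000040 ! scan direction

[Term]
id: IMS:1000403
name: left right
is_a: IMS:1000040 ! scan direction

[Term]
id: IMS:1000404
name: right left
is_a: IMS:1000040 ! scan direction

[Term]
id: IMS:1000041
name: scan pattern

[Term]
id: IMS:1000410
name: meandering
is_a: IMS:1000041 ! scan pattern

[Term]
id: IMS:1000413
name: flyback
is_a: IMS:1000041 ! scan pattern

[Term]
id: IMS:1000048
name: scan type

[Term]
id: IMS:1000480
name: horizontal line scan
is_a: IMS:1000048 ! scan type

[Term]
id: IMS:1000481
name: vertical line scan
is_a: IMS:1000048 ! scan type

[Term]
id: IMS:1000049
name: line scan direction

[Term]
id: IMS:1000490
name: linescan right left
is_a: IMS:1000049 ! line scan direction

[Term]
id: IMS:1000491
name: linescan left right
is_a: IMS:1000049 ! line scan direction

[Term]
id: IMS:1000492
name: linescan bottom up
is_a: IMS:1000049 ! line scan direction

[Term]
id: IMS:1000493
name: linescan top down
is_a: IMS:1000049 ! line scan direction

[Term]
id: IMS:1000042
name: max count of pixels x

[Term]
id: IMS:1000043
name: max count of pixels y

[Term]
id: IMS:1000044
name: max dimension x

[Term]
id: IMS:1000045
name: max dimension y

[Term]
id: IMS:1000046
name: pixel size x

[Term]
id: IMS:1000047
name: pixel size y

[Term]
id: IMS:1000053
name: absolute position offset x

[Term]
id: IMS:1000054
name: absolute position offset y

[Term]
id: IMS:1000202
name: target material

[Term]
id: IMS:1000802
name: spatial resolution

[Term]
id: IMS:1000806
name: position accuracy

[Term]
id: IMS:1000835
name: matrix solution
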