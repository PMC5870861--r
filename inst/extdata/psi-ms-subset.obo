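format-version: 1.2
data-version: 4.1.30-subset
ontology: ms
remark: Reduced test subset of the PSI-MS controlled vocabulary covering the term subtrees used by the default mzML extraction ruleset. Not the full vocabulary.

[Term]
id: MS:1000031
name: instrument model

[Term]
id: MS:1000483
name: Thermo Fisher Scientific instrument model
is_a: MS:1000031 ! instrument model

[Term]
id: MS:1000126
name: Waters instrument model
is_a: MS:1000031 ! instrument model

[Term]
id: MS:1000122
name: Bruker Daltonics instrument model
is_a: MS:1000031 ! instrument model

[Term]
id: MS:1000121
name: SCIEX instrument model
is_a: MS:1000031 ! instrument model

[Term]
id: MS:1000490
name: Agilent instrument model
is_a: MS:1000031 ! instrument model

[Term]
id: MS:1000449
name: LTQ Orbitrap
is_a: MS:1000483 ! Thermo Fisher Scientific instrument model

[Term]
id: MS:1000556
name: LTQ Orbitrap XL
is_a: MS:1000483 ! Thermo Fisher Scientific instrument model

[Term]
id: MS:1001911
name: Q Exactive
is_a: MS:1000483 ! Thermo Fisher Scientific instrument model

[Term]
id: MS:1001790
name: SYNAPT G2-S
is_a: MS:1000126 ! Waters instrument model

[Term]
id: MS:1001547
name: micrOTOF-Q
is_a: MS:1000122 ! Bruker Daltonics instrument model

[Term]
id: MS:1000932
name: TripleTOF 5600
is_a: MS:1000121 ! SCIEX instrument model

[Term]
id: MS:1000471
name: 6520 Quadrupole Time-of-Flight LC/MS
is_a: MS:1000490 ! Agilent instrument model

[Term]
id: MS:1000008
name: ionization type

[Term]
id: MS:1000073
name: electrospray ionization
is_a: MS:1000008 ! ionization type

[Term]
id: MS:1000398
name: nanoelectrospray
is_a: MS:1000073 ! electrospray ionization

[Term]
id: MS:1000075
name: matrix-assisted laser desorption ionization
is_a: MS:1000008 ! ionization type

[Term]
id: MS:1000071
name: chemical ionization
is_a: MS:1000008 ! ionization type

[Term]
id: MS:1000443
name: mass analyzer type

[Term]
id: MS:1000484
name: orbitrap
is_a: MS:1000443 ! mass analyzer type

[Term]
id: MS:1000081
name: quadrupole
is_a: MS:1000443 ! mass analyzer type

[Term]
id: MS:1000084
name: time-of-flight
is_a: MS:1000443 ! mass analyzer type

[Term]
id: MS:1000264
name: ion trap
is_a: MS:1000443 ! mass analyzer type

[Term]
id: MS:1000079
name: fourier transform ion cyclotron resonance mass spectrometer
is_a: MS:1000443 ! mass analyzer type

[Term]
id: MS:1000026
name: detector type

[Term]
id: MS:1000253
name: electron multiplier
is_a: MS:1000026 ! detector type

[Term]
id: MS:1000624
name: inductive detector
is_a: MS:1000026 ! detector type

[Term]
id: MS:1000116
name: photomultiplier
is_a: MS:1000026 ! detector type

[Term]
id: MS:1000531
name: software

[Term]
id: MS:1000532
name: Xcalibur
is_a: MS:1000531 ! software

[Term]
id: MS:1000615
name: ProteoWizard software
is_a: MS:1000531 ! software

[Term]
id: MS:1002205
name: ProteoWizard msconvert
is_a: MS:1000615 ! ProteoWizard software

[Term]
id: MS:1000717
name: CompassXport
is_a: MS:1000531 ! software

[Term]
id: MS:1000452
name: data transformation

[Term]
id: MS:1000530
name: file format conversion
is_a: MS:1000452 ! data transformation

[Term]
id: MS:1000544
name: Conversion to mzML
is_a: MS:1000530 ! file format conversion

[Term]
id: MS:1000545
name: Conversion to mzXML
is_a: MS:1000530 ! file format conversion

[Term]
id: MS:1000543
name: data processing action
is_a: MS:1000452 ! data transformation

[Term]
id: MS:1000592
name: smoothing
is_a: MS:1000543 ! data processing action

[Term]
id: MS:1000593
name: baseline reduction
is_a: MS:1000543 ! data processing action

[Term]
id: MS:1000594
name: low intensity data point removal
is_a: MS:1000543 ! data processing action

[Term]
id: MS:1000033
name: deisotoping
is_a: MS:1000543 ! data processing action

[Term]
id: MS:1000034
name: charge deconvolution
is_a: MS:1000543 ! data processing action

[Term]
id: MS:1000560
name: mass spectrometer file format

[Term]
id: MS:1000563
name: Thermo RAW format
is_a: MS:1000560 ! mass spectrometer file format

[Term]
id: MS:1000562
name: ABI WIFF format
is_a: MS:1000560 ! mass spectrometer file format

[Term]
id: MS:1000584
name: mzML format
is_a: MS:1000560 ! mass spectrometer file format

[Term]
id: MS:1000767
name: native spectrum identifier format

[Term]
id: MS:1000768
name: Thermo nativeID format
is_a: MS:1000767 ! native spectrum identifier format

[Term]
id: MS:1000774
name: multiple peak list nativeID format
is_a: MS:1000767 ! native spectrum identifier format

[Term]
id: MS:1000561
name: data file checksum type

[Term]
id: MS:1000568
name: MD5
is_a: MS:1000561 ! data file checksum type

[Term]
id: MS:1000569
name: SHA-1
is_a: MS:1000561 ! data file checksum type

[Term]
id: MS:1000524
name: data file content

[Term]
id: MS:1000294
name: mass spectrum
is_a: MS:1000524 ! data file content

[Term]
id: MS:1000579
name: MS1 spectrum
is_a: MS:1000294 ! mass spectrum

[Term]
id: MS:1000580
name: MSn spectrum
is_a: MS:1000294 ! mass spectrum

[Term]
id: MS:1000525
name: spectrum representation

[Term]
id: MS:1000127
name: centroid spectrum
is_a: MS:1000525 ! spectrum representation

[Term]
id: MS:1000128
name: profile spectrum
is_a: MS:1000525 ! spectrum representation

[Term]
id: MS:1000465
name: scan polarity

[Term]
id: MS:1000129
name: negative scan
is_a: MS:1000465 ! scan polarity

[Term]
id: MS:1000130
name: positive scan
is_a: MS:1000465 ! scan polarity

[Term]
id: MS:1000572
name: binary data compression type

[Term]
id: MS:1000574
name: zlib compression
is_a: MS:1000572 ! binary data compression type

[Term]
id: MS:1000576
name: no compression
is_a: MS:1000572 ! binary data compression type

[Term]
id: MS:1000586
name: contact name

[Term]
id: MS:1000590
name: contact affiliation

[Term]
id: MS:1000529
name: instrument serial number

[Term]
id: MS:1000032
name: customization

[Term]
id: MS:1000501
name: scan window lower limit

[Term]
id: MS:1000500
name: scan window upper limit

[Term]
id: MS:1000511
name: ms level

[Term]
id: MS:1000030
name: vendor
is_obsolete: true
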