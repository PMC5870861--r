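format-version: 1.2
data-version: 1.1.0-subset
ontology: nmrcv
remark: Reduced test subset of the NMR controlled vocabulary covering the term subtrees used by the default nmrML extraction ruleset. Accessions are synthetic placeholders in the nmrCV id range; not the full vocabulary.

[Term]
id: NMR:1400014
name: NMR instrument

[Term]
id: NMR:1400015
name: Bruker NMR instrument
is_a: NMR:1400014 ! NMR instrument

[Term]
id: NMR:1400016
name: Varian NMR instrument
is_a: NMR:1400014 ! NMR instrument

[Term]
id: NMR:1400017
name: JEOL NMR instrument
is_a: NMR:1400014 ! NMR instrument

[Term]
id: NMR:1400018
name: Bruker Avance III 600
is_a: NMR:1400015 ! Bruker NMR instrument

[Term]
id: NMR:1400019
name: Bruker Avance II 500
is_a: NMR:1400015 ! Bruker NMR instrument

[Term]
id: NMR:1400020
name: Varian INOVA 600
is_a: NMR:1400016 ! Varian NMR instrument

[Term]
id: NMR:1400021
name: JEOL ECA 600
is_a: NMR:1400017 ! JEOL NMR instrument

[Term]
id: NMR:1400121
name: NMR probe

[Term]
id: NMR:1400122
name: cryoprobe
is_a: NMR:1400121 ! NMR probe

[Term]
id: NMR:1400123
name: inverse triple resonance probe
is_a: NMR:1400121 ! NMR probe

[Term]
id: NMR:1400224
name: software

[Term]
id: NMR:1400225
name: TopSpin
is_a: NMR:1400224 ! software

[Term]
id: NMR:1400226
name: VnmrJ
is_a: NMR:1400224 ! software

[Term]
id: NMR:1400227
name: Delta
is_a: NMR:1400224 ! software

[Term]
id: NMR:1400034
name: instrument serial number

[Term]
id: NMR:1400151
name: nucleus

[Term]
id: NMR:1400152
name: 1H
is_a: NMR:1400151 ! nucleus

[Term]
id: NMR:1400153
name: 13C
is_a: NMR:1400151 ! nucleus

[Term]
id: NMR:1400154
name: 15N
is_a: NMR:1400151 ! nucleus

[Term]
id: NMR:1400155
name: 31P
is_a: NMR:1400151 ! nucleus

[Term]
id: NMR:1400311
name: NMR solvent

[Term]
id: NMR:1400312
name: deuterium oxide
is_a: NMR:1400311 ! NMR solvent

[Term]
id: NMR:1400313
name: deuterated chloroform
is_a: NMR:1400311 ! NMR solvent

[Term]
id: NMR:1400314
name: DMSO-d6
is_a: NMR:1400311 ! NMR solvent

[Term]
id: NMR:1400321
name: solvent suppression method

[Term]
id: NMR:1400322
name: presaturation
is_a: NMR:1400321 ! solvent suppression method

[Term]
id: NMR:1400323
name: WATERGATE
is_a: NMR:1400321 ! solvent suppression method

[Term]
id: NMR:1400324
name: excitation sculpting
is_a: NMR:1400321 ! solvent suppression method

[Term]
id: NMR:1400331
name: NMR tube type

[Term]
id: NMR:1400332
name: 5 mm NMR tube
is_a: NMR:1400331 ! NMR tube type

[Term]
id: NMR:1400333
name: 3 mm NMR tube
is_a: NMR:1400331 ! NMR tube type

[Term]
id: NMR:1400341
name: decoupling method

[Term]
id: NMR:1400342
name: WALTZ-16
is_a: NMR:1400341 ! decoupling method

[Term]
id: NMR:1400343
name: GARP
is_a: NMR:1400341 ! decoupling method

[Term]
id: NMR:1400351
name: data transformation

[Term]
id: NMR:1400352
name: Fourier transform
is_a: NMR:1400351 ! data transformation

[Term]
id: NMR:1400353
name: magnitude calculation
is_a: NMR:1400351 ! data transformation

[Term]
id: NMR:1400361
name: window function

[Term]
id: NMR:1400362
name: exponential window function
is_a: NMR:1400361 ! window function

[Term]
id: NMR:1400363
name: Gaussian window function
is_a: NMR:1400361 ! window function

[Term]
id: NMR:1400364
name: sine bell window function
is_a: NMR:1400361 ! window function

[Term]
id: NMR:1400371
name: baseline correction method

[Term]
id: NMR:1400372
name: polynomial baseline correction
is_a: NMR:1400371 ! baseline correction method

[Term]
id: NMR:1400381
name: chemical shift calibration compound

[Term]
id: NMR:1400382
name: TSP
is_a: NMR:1400381 ! chemical shift calibration compound

[Term]
id: NMR:1400383
name: DSS
is_a: NMR:1400381 ! chemical shift calibration compound

[Term]
id: NMR:1400384
name: TMS
is_a: NMR:1400381 ! chemical shift calibration compound

[Term]
id: NMR:1400391
name: shimming method

[Term]
id: NMR:1400392
name: gradient shimming
is_a: NMR:1400391 ! shimming method

[Term]
id: NMR:1400401
name: detection method

[Term]
id: NMR:1400402
name: quadrature detection
is_a: NMR:1400401 ! detection method

[Term]
id: NMR:1400285
name: NMR raw data file format

[Term]
id: NMR:1400286
name: Bruker FID format
is_a: NMR:1400285 ! NMR raw data file format

[Term]
id: NMR:1400287
name: nmrML format
is_a: NMR:1400285 ! NMR raw data file format

[Term]
id: NMR:1400291
name: data file checksum type

[Term]
id: NMR:1400292
name: MD5
is_a: NMR:1400291 ! data file checksum type

[Term]
id: NMR:1400293
name: SHA-1
is_a: NMR:1400291 ! data file checksum type

[Term]
id: NMR:1400295
name: data file content

[Term]
id: NMR:1400296
name: free induction decay
is_a: NMR:1400295 ! data file content

[Term]
id: NMR:1400297
name: processed NMR spectrum
is_a: NMR:1400295 ! data file content

[Term]
id: NMR:1400301
name: contact name

[Term]
id: NMR:1400302
name: contact affiliation
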