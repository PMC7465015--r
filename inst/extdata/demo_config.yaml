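# Demo pipeline configuration: toy two-chromosome genome with one planted
# retrocopy, scanned and characterized end to end.
seed: 42
sim:
  readLen: 150
  insertMean: 400
  insertSd: 50
  coverage: 20
  errorRate: 0.001
genome:
  chromLengths:
    chrA: 200000
    chrB: 200000
insertions: 1
scan:
  minJunction: 3
  minTrans: 3
ecrBed: demo_ecr.bed
populationVcf: demo_population.vcf
genotypeTsv: demo_genotypes.tsv
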