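# Four-node logical model of the mammalian p53-Mdm2 network.
# Node order is semantic: state codes read p53, Mdm2cyt, Mdm2nuc, DNAdam.
node p53 max=2
node Mdm2cyt max=2
node Mdm2nuc max=1
node DNAdam max=1
edge p53 -> Mdm2nuc t=1 sign=-
edge p53 -> Mdm2cyt t=2 sign=+
edge p53 -> DNAdam t=2 sign=-
edge Mdm2cyt -> Mdm2nuc t=1 sign=+
edge Mdm2cyt -> Mdm2nuc t=2 sign=+
edge Mdm2nuc -> p53 t=1 sign=-
edge DNAdam -> DNAdam t=1 sign=+
edge DNAdam -> Mdm2nuc t=1 sign=-
rule p53 := 2 <- !Mdm2nuc
rule Mdm2cyt := 2 <- p53
rule Mdm2cyt := 1 <- !p53
rule Mdm2nuc := 1 <- Mdm2cyt:2 | (Mdm2cyt:1 & !p53 & !DNAdam)
rule DNAdam := 1 <- DNAdam & !p53
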