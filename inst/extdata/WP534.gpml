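<?xml version="1.0" encoding="UTF-8"?>
<Pathway xmlns="http://pathvisio.org/GPML/2013a" Name="Glycolysis and Gluconeogenesis" Organism="Homo sapiens">
  <DataNode TextLabel="Glucose" GraphId="dba83" Type="Metabolite">
    <Graphics CenterX="279.0" CenterY="468.0" Width="112.0" Height="20.0" ZOrder="32768"/>
    <Xref Database="ChEBI" ID="CHEBI:4167"/>
  </DataNode>
</Pathway>
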