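<?xml version="1.0" encoding="UTF-8"?>
<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0" minorVersion="0">
  <entry>
    <experimentList>
      <experimentDescription id="1">
        <bibref>
          <xref>
            <primaryRef db="pubmed" id="7000011"/>
          </xref>
        </bibref>
        <hostOrganismList>
          <hostOrganism ncbiTaxId="9606">
            <names>
              <shortLabel>human</shortLabel>
            </names>
          </hostOrganism>
        </hostOrganismList>
        <interactionDetectionMethod>
          <names>
            <shortLabel>affinity chromatography technology</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0004" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactionDetectionMethod>
      </experimentDescription>
    </experimentList>
    <interactorList>
      <interactor id="2">
        <names>
          <shortLabel>cedar_promoter</shortLabel>
          <fullName>cedar gene upstream region</fullName>
        </names>
        <interactorType>
          <names>
            <shortLabel>dna</shortLabel>
            <fullName>deoxyribonucleic acid</fullName>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0319" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <organism ncbiTaxId="9606">
          <names>
            <shortLabel>human</shortLabel>
          </names>
        </organism>
      </interactor>
      <interactor id="3">
        <names>
          <shortLabel>dunlin_tf</shortLabel>
        </names>
        <interactorType>
          <names>
            <shortLabel>protein</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0326" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactorType>
        <organism ncbiTaxId="9606">
          <names>
            <shortLabel>human</shortLabel>
          </names>
        </organism>
      </interactor>
    </interactorList>
    <interactionList>
      <interaction id="5">
        <experimentList>
          <experimentRef>1</experimentRef>
        </experimentList>
        <participantList>
          <participant id="6">
            <interactorRef>2</interactorRef>
            <featureList>
              <feature id="4">
                <names>
                  <shortLabel>promoter region</shortLabel>
                </names>
                <featureType>
                  <names>
                    <shortLabel>binding site</shortLabel>
                  </names>
                  <xref>
                    <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0117" refType="identity" refTypeAc="MI:0356"/>
                  </xref>
                </featureType>
                <featureRangeList>
                  <featureRange>
                    <startStatus>
                      <names>
                        <shortLabel>certain</shortLabel>
                      </names>
                      <xref>
                        <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0335" refType="identity" refTypeAc="MI:0356"/>
                      </xref>
                    </startStatus>
                    <begin position="-2000"/>
                    <endStatus>
                      <names>
                        <shortLabel>certain</shortLabel>
                      </names>
                      <xref>
                        <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0335" refType="identity" refTypeAc="MI:0356"/>
                      </xref>
                    </endStatus>
                    <end position="-1"/>
                  </featureRange>
                </featureRangeList>
              </feature>
            </featureList>
          </participant>
          <participant id="7">
            <interactorRef>3</interactorRef>
            <experimentalRoleList>
              <experimentalRole>
                <names>
                  <shortLabel>bait</shortLabel>
                </names>
                <xref>
                  <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0496" refType="identity" refTypeAc="MI:0356"/>
                </xref>
              </experimentalRole>
            </experimentalRoleList>
          </participant>
        </participantList>
        <interactionType>
          <names>
            <shortLabel>physical association</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0915" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactionType>
      </interaction>
    </interactionList>
  </entry>
</entrySet>
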