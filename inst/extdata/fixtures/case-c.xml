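<?xml version="1.0" encoding="UTF-8"?>
<entrySet xmlns="http://psi.hupo.org/mi/mif300" level="3" version="0" minorVersion="0">
  <entry>
    <experimentList>
      <experimentDescription id="1">
        <bibref>
          <xref>
            <primaryRef db="pubmed" id="7000013"/>
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
            <shortLabel>coimmunoprecipitation</shortLabel>
          </names>
          <xref>
            <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0019" refType="identity" refTypeAc="MI:0356"/>
          </xref>
        </interactionDetectionMethod>
      </experimentDescription>
    </experimentList>
    <interactorList>
      <interactor id="2">
        <names>
          <shortLabel>alder_p</shortLabel>
        </names>
        <xref>
          <primaryRef db="uniprotkb" id="X00001"/>
        </xref>
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
      <interactor id="3">
        <names>
          <shortLabel>birch_p</shortLabel>
        </names>
        <xref>
          <primaryRef db="uniprotkb" id="X00002"/>
        </xref>
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
      <interaction id="7">
        <experimentList>
          <experimentRef>1</experimentRef>
        </experimentList>
        <participantList>
          <participant id="5">
            <interactorRef>2</interactorRef>
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
            <featureList>
              <feature id="4">
                <names>
                  <shortLabel>phosphotyrosine site</shortLabel>
                </names>
                <featureType>
                  <names>
                    <shortLabel>observed-ptm</shortLabel>
                  </names>
                  <xref>
                    <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0925" refType="identity" refTypeAc="MI:0356"/>
                  </xref>
                </featureType>
                <featureDetectionMethod>
                  <names>
                    <shortLabel>identification by antibody</shortLabel>
                  </names>
                  <xref>
                    <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0421" refType="identity" refTypeAc="MI:0356"/>
                  </xref>
                </featureDetectionMethod>
                <featureDetectionMethod>
                  <names>
                    <shortLabel>detection by mass spectrometry</shortLabel>
                  </names>
                  <xref>
                    <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0943" refType="identity" refTypeAc="MI:0356"/>
                  </xref>
                </featureDetectionMethod>
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
                    <begin position="77"/>
                    <endStatus>
                      <names>
                        <shortLabel>certain</shortLabel>
                      </names>
                      <xref>
                        <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0335" refType="identity" refTypeAc="MI:0356"/>
                      </xref>
                    </endStatus>
                    <end position="77"/>
                  </featureRange>
                </featureRangeList>
              </feature>
            </featureList>
          </participant>
          <participant id="6">
            <interactorRef>3</interactorRef>
            <experimentalRoleList>
              <experimentalRole>
                <names>
                  <shortLabel>prey</shortLabel>
                </names>
                <xref>
                  <primaryRef db="psi-mi" dbAc="MI:0488" id="MI:0498" refType="identity" refTypeAc="MI:0356"/>
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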